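#' Assembled finite-element model of a substrate, ready to solve
#'
#' Bundles the mesh, the assembled stiffness matrix and a factorization
#' cache.  Building the context once and passing it to several recoveries
#' or forward solves on the same grid amortizes assembly and factorization,
#' which dominate the cost of every operation.
#'
#' @param substrate A [substrate_model()].
#' @param grid A [surface_grid()]; becomes the mesh's top-surface lattice.
#' @param spacing_z Target vertical spacing, um; defaults to half the
#'   in-plane spacing (see [mesh_from_substrate()]).
#' @param options A [fem_solver_options()].
#' @return An object of class `fem_context`.
#' @export
fem_context <- function(substrate, grid, spacing_z = NULL,
                        options = fem_solver_options()) {
  mesh <- mesh_from_substrate(substrate, grid, spacing_z)
  K <- assemble_global(mesh, substrate)
  structure(
    list(substrate = substrate, grid = grid, mesh = mesh, K = K,
         options = options, cache = new.env(parent = emptyenv())),
    class = "fem_context"
  )
}

#' @export
print.fem_context <- function(x, ...) {
  cat("<fem_context> E =", x$substrate$youngs_modulus, "kPa, nu =",
      x$substrate$poissons_ratio, "\n  ")
  print(x$mesh)
  invisible(x)
}

# Resolve a context: use the one supplied or build a fresh one.
resolve_context <- function(context, substrate, grid, options) {
  if (!is.null(context)) {
    stopifnot(inherits(context, "fem_context"))
    if (!grids_identical(context$grid, grid)) {
      stop("supplied fem_context was built for a different surface grid")
    }
    if (!identical(context$substrate[c("youngs_modulus", "poissons_ratio", "thickness")],
                   substrate[c("youngs_modulus", "poissons_ratio", "thickness")])) {
      stop("supplied fem_context was built for a different substrate")
    }
    return(context)
  }
  fem_context(substrate, grid, options = options)
}

# Base mixed BC for every recovery/forward problem: bottom and lateral
# walls clamped (gel bonded to glass; walls far from the cells).
clamped_base_bc <- function(mesh) {
  n_dof <- 3 * mesh_n_nodes(mesh)
  bc <- mixed_bc_set(n_dof)
  fixed <- fixed_boundary_nodes(mesh)
  dofs <- node_dof(rep(fixed, each = 3L), rep(1:3, length(fixed)))
  prescribe_displacement(bc, dofs, 0)
}

# Displacement/force matrices for the top surface <-> DOF vector plumbing.
surface_dofs <- function(mesh, axis) {
  node_dof(surface_node_matrix(mesh), axis)  # nx x ny matrix of DOF ids
}
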