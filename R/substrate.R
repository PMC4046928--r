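#' Elastic substrate model
#'
#' Describes the polyacrylamide (or other linear-elastic) gel slab the cells
#' sit on: material constants plus slab geometry.  All quantities use the
#' internal unit system kPa / micrometre / nanonewton, chosen so that
#' 1 kPa x 1 um^2 = 1 nN and no conversion factors appear anywhere.
#'
#' @param youngs_modulus Young's modulus of the gel, kPa. Must be positive.
#' @param poissons_ratio Poisson's ratio, dimensionless, in `[0, 0.5)`.
#'   The incompressible limit 0.5 is rejected: the standard displacement
#'   formulation used here is singular there.  Polyacrylamide gels measure
#'   around 0.45-0.48.
#' @param thickness Gel thickness, um (distance from the glass-bonded bottom
#'   to the free top surface).
#' @param lateral_size_x,lateral_size_y Lateral extent of the modelled slab,
#'   um. May be `NA` when the extent is taken from a surface grid later.
#'
#' @return An object of class `substrate_model`.
#' @export
#' @examples
#' substrate_model(1, 0.45, 70)
substrate_model <- function(youngs_modulus, poissons_ratio, thickness,
                            lateral_size_x = NA_real_, lateral_size_y = NA_real_) {
  if (!is.numeric(youngs_modulus) || length(youngs_modulus) != 1L ||
      !is.finite(youngs_modulus) || youngs_modulus <= 0) {
    stop("`youngs_modulus` must be a single positive number (kPa)")
  }
  if (!is.numeric(poissons_ratio) || length(poissons_ratio) != 1L ||
      !is.finite(poissons_ratio) || poissons_ratio < 0 || poissons_ratio >= 0.5) {
    stop("`poissons_ratio` must lie in [0, 0.5); the incompressible limit ",
         "0.5 is singular for the displacement formulation")
  }
  if (!is.numeric(thickness) || length(thickness) != 1L ||
      !is.finite(thickness) || thickness <= 0) {
    stop("`thickness` must be a single positive number (um)")
  }
  for (nm in c("lateral_size_x", "lateral_size_y")) {
    v <- get(nm)
    if (!is.na(v) && (!is.numeric(v) || v <= 0)) {
      stop("`", nm, "` must be positive (um) or NA")
    }
  }
  structure(
    list(
      youngs_modulus = as.numeric(youngs_modulus),
      poissons_ratio = as.numeric(poissons_ratio),
      thickness = as.numeric(thickness),
      lateral_size_x = as.numeric(lateral_size_x),
      lateral_size_y = as.numeric(lateral_size_y)
    ),
    class = "substrate_model"
  )
}

#' @export
print.substrate_model <- function(x, ...) {
  cat("<substrate_model>  E =", x$youngs_modulus, "kPa,  nu =", x$poissons_ratio,
      ",  thickness =", x$thickness, "um\n")
  if (!is.na(x$lateral_size_x)) {
    cat("  lateral extent:", x$lateral_size_x, "x", x$lateral_size_y, "um\n")
  }
  invisible(x)
}

#' Regular surface grid
#'
#' The common node lattice shared by displacement fields, masks and traction
#' fields: `nx` x `ny` nodes with uniform spacing, lower-left node at
#' `origin`.  Node `(i, j)` (1-based) sits at
#' `origin + ((i-1) * sx, (j-1) * sy)` um; x increases with `i`, y with `j`.
#'
#' @param nx,ny Node counts per axis (>= 2).
#' @param spacing Grid spacing um; a scalar or `c(sx, sy)`.
#' @param origin `c(x0, y0)` um of the lower-left node.
#' @return An object of class `surface_grid`.
#' @export
surface_grid <- function(nx, ny, spacing, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L) {
    stop("grid needs at least 2 nodes per axis")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be one or two positive numbers (um)")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop("`origin` must be c(x0, y0)")
  }
  structure(
    list(nx = nx, ny = ny, spacing = spacing, origin = origin),
    class = "surface_grid"
  )
}

#' @export
print.surface_grid <- function(x, ...) {
  cat("<surface_grid> ", x$nx, "x", x$ny, "nodes, spacing",
      paste(signif(x$spacing, 6), collapse = " x "),
      "um, origin (", paste(signif(x$origin, 6), collapse = ", "), ") um\n")
  invisible(x)
}

#' Node x coordinates of a surface grid
#' @param grid A [surface_grid()].
#' @return Numeric vector of length `nx`.
#' @export
grid_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 1) * grid$spacing[1]

#' Node y coordinates of a surface grid
#' @param grid A [surface_grid()].
#' @return Numeric vector of length `ny`.
#' @export
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 1) * grid$spacing[2]

grid_extent <- function(grid) {
  c((grid$nx - 1L) * grid$spacing[1], (grid$ny - 1L) * grid$spacing[2])
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$spacing)))
}

#' Structured hexahedral mesh of the gel slab
#'
#' Node `(i, j, k)` (1-based) sits at
#' `(x0 + (i-1) sx, y0 + (j-1) sy, (k-1) sz)`.  `k = nz` is the free top
#' surface carrying the cells; `k = 1` is the glass-bonded bottom.  Nodes
#' are numbered lexicographically, `i` fastest, then `j`, then `k`; each
#' node carries three degrees of freedom ordered (x, y, z).
#'
#' @param nx,ny,nz Node counts per axis (>= 2).
#' @param spacing `c(sx, sy, sz)` um, all positive.
#' @param origin `c(x0, y0)` um of the surface grid.
#' @return An object of class `hex_mesh`.
#' @export
hex_mesh <- function(nx, ny, nz, spacing, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(is.na(c(nx, ny, nz))) || any(c(nx, ny, nz) < 2L)) {
    stop("mesh needs at least 2 nodes per axis")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be c(sx, sy, sz), all positive (um)")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop("`origin` must be c(x0, y0)")
  }
  structure(
    list(nx = nx, ny = ny, nz = nz, spacing = spacing, origin = origin),
    class = "hex_mesh"
  )
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("<hex_mesh> ", x$nx, "x", x$ny, "x", x$nz, "nodes (",
      mesh_n_nodes(x), "nodes,", 3 * mesh_n_nodes(x), "DOFs ), spacing",
      paste(signif(x$spacing, 6), collapse = " x "), "um\n")
  invisible(x)
}

#' Number of nodes in a mesh
#' @param mesh A [hex_mesh()].
#' @return Integer node count `nx * ny * nz`.
#' @export
mesh_n_nodes <- function(mesh) as.double(mesh$nx) * mesh$ny * mesh$nz

#' Linear node index from (i, j, k)
#'
#' Lexicographic, `i` fastest.  Vectorised over `i`, `j`, `k`.
#' @param mesh A [hex_mesh()].
#' @param i,j,k 1-based axis indices.
#' @return Numeric (double) node indices.
#' @export
node_index <- function(mesh, i, j, k) {
  i + (j - 1) * mesh$nx + (k - 1) * mesh$nx * mesh$ny
}

#' Degree-of-freedom indices for nodes
#' @param nodes Node indices.
#' @param axis 1 = x, 2 = y, 3 = z.
#' @return DOF indices (3 per node, node-major, axis fastest).
#' @export
node_dof <- function(nodes, axis) 3 * (nodes - 1) + axis

#' Top-surface node indices of a mesh, as an nx x ny matrix
#' @param mesh A [hex_mesh()].
#' @return Matrix `[i, j]` of node indices on the free surface `k = nz`.
#' @export
surface_node_matrix <- function(mesh) {
  outer(seq_len(mesh$nx), seq_len(mesh$ny),
        function(i, j) node_index(mesh, i, j, mesh$nz))
}

#' Surface grid of a mesh's free top surface
#' @param mesh A [hex_mesh()].
#' @return The [surface_grid()] spanned by the top-surface nodes.
#' @export
mesh_surface_grid <- function(mesh) {
  surface_grid(mesh$nx, mesh$ny, mesh$spacing[1:2], mesh$origin)
}

#' Nodes on the fixed boundary (bottom plus the four lateral walls)
#'
#' These are the nodes clamped to zero displacement in every traction
#' recovery and forward simulation: the gel is bonded to glass at the bottom
#' and the walls are placed far enough from the cells that clamping them is
#' inconsequential.
#'
#' @param mesh A [hex_mesh()].
#' @return Sorted vector of node indices.
#' @export
fixed_boundary_nodes <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  idx <- array(FALSE, dim = c(nx, ny, nz))
  idx[, , 1] <- TRUE          # glass-bonded bottom
  idx[1, , ] <- TRUE          # four lateral walls
  idx[nx, , ] <- TRUE
  idx[, 1, ] <- TRUE
  idx[, ny, ] <- TRUE
  which(idx)
}

#' Interior free-surface nodes (top surface minus the wall ring)
#' @param mesh A [hex_mesh()].
#' @return Vector of node indices on `k = nz` not belonging to a wall.
#' @export
free_surface_nodes <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  ii <- matrix(seq_len(nx), nx, ny)
  jj <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  keep <- ii > 1L & ii < nx & jj > 1L & jj < ny
  sn <- surface_node_matrix(mesh)
  sort(sn[keep])
}

#' Build the mesh realizing a substrate over a given surface grid
#'
#' The vertical spacing is chosen as close as possible to a target while
#' spanning the thickness exactly.  The default target is half the
#' in-plane spacing: displacement and stress gradients are steepest just
#' below the loaded surface, and refining vertically costs far less than
#' refining laterally (2x DOFs instead of 4x) while controlling the
#' dominant discretization error of surface-load problems.
#'
#' @param substrate A [substrate_model()].
#' @param grid A [surface_grid()] giving the lateral node lattice.
#' @param spacing_z Target vertical spacing um; default half the mean
#'   in-plane spacing.
#' @return A [hex_mesh()] whose top surface coincides with `grid`.
#' @export
mesh_from_substrate <- function(substrate, grid, spacing_z = NULL) {
  stopifnot(inherits(substrate, "substrate_model"), inherits(grid, "surface_grid"))
  ext <- grid_extent(grid)
  for (ax in 1:2) {
    ls <- c(substrate$lateral_size_x, substrate$lateral_size_y)[ax]
    if (!is.na(ls) && abs(ls - ext[ax]) > 1e-6 * max(1, ls)) {
      stop("substrate lateral size (", ls, " um) does not match the grid extent (",
           signif(ext[ax], 8), " um) on axis ", c("x", "y")[ax])
    }
  }
  if (is.null(spacing_z)) spacing_z <- mean(grid$spacing) / 2
  n_el_z <- max(2L, as.integer(round(substrate$thickness / spacing_z)))
  hex_mesh(
    nx = grid$nx, ny = grid$ny, nz = n_el_z + 1L,
    spacing = c(grid$spacing, substrate$thickness / n_el_z),
    origin = grid$origin
  )
}
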