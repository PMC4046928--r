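#' Recommended distance between labelled nodes and the lateral walls
#'
#' The walls are clamped, so they must sit far enough from the cells that
#' the clamping does not distort the local solution.  The rule used by the
#' fixture generators: at least the gel thickness, at least three quarters
#' of the mask bounding-box diagonal, and never less than 30 um.
#'
#' @param thickness Gel thickness, um.
#' @param bbox_diagonal Diagonal of the labelled region's bounding box, um.
#' @return Margin, um.
#' @export
recommended_margin <- function(thickness, bbox_diagonal = 0) {
  max(thickness, 0.75 * bbox_diagonal, 30)
}

# Symmetric grid: node at x = 0, walls at least `half_extent` from centre.
centred_grid <- function(half_extent_x, half_extent_y, spacing) {
  nhx <- ceiling(half_extent_x / spacing)
  nhy <- ceiling(half_extent_y / spacing)
  surface_grid(2L * nhx + 1L, 2L * nhy + 1L, spacing,
               origin = c(-nhx * spacing, -nhy * spacing))
}

# Label grid nodes lying inside circles; first circle wins ties (circles in
# fixtures never overlap).
rasterize_disks <- function(grid, centers, radius) {
  labels <- matrix(0L, grid$nx, grid$ny)
  xs <- grid_x(grid); ys <- grid_y(grid)
  for (c_i in seq_len(nrow(centers))) {
    inside <- outer(xs - centers[c_i, 1], ys - centers[c_i, 2],
                    function(dx, dy) dx^2 + dy^2) <= radius^2
    labels[inside & labels == 0L] <- c_i
  }
  labels
}

# Remove the (tiny, floating-point) net in-plane force of every cluster by
# spreading the opposite of the net over the loaded nodes.  Construction
# patterns are symmetric, so the correction is at rounding level, but the
# self-equilibration invariant is then exact by construction.
balance_clusters <- function(fx, fy, labels) {
  for (l in sort(unique(labels[labels > 0L]))) {
    loaded <- labels == l & (abs(fx) > 0 | abs(fy) > 0)
    n <- sum(loaded)
    if (n == 0L) next
    fx[loaded] <- fx[loaded] - sum(fx[labels == l]) / n
    fy[loaded] <- fy[loaded] - sum(fy[labels == l]) / n
  }
  list(fx = fx, fy = fy)
}

#' Two-cell validation fixture
#'
#' The classic two-cell geometry used to validate traction recovery by
#' round trip: two circular "cells" (default 20 um diameter, edges 10 um
#' apart) on a 1 kPa, 70 um thick gel.  A self-equilibrated in-plane force
#' field acts within each circle; the default `contractile_pair` pattern
#' loads the two halves of each circle with equal and opposite forces along
#' the inter-cell axis, mimicking a contracting cell.  `ring` loads an
#' annulus (radii 0.5 R to R) with radially inward forces.
#'
#' Optionally a balanced out-of-plane component of magnitude
#' `fz_ratio * |F_inplane|` (sign following the side of the cell centre) is
#' added, used by the Poisson-ratio decoupling study.
#'
#' @param diameter Cell diameter, um.
#' @param gap Edge-to-edge distance between the two circles, um.
#' @param E Gel Young's modulus, kPa.
#' @param nu Gel Poisson's ratio.
#' @param thickness Gel thickness, um.
#' @param peak_force Peak nodal force magnitude, nN.
#' @param pattern `"contractile_pair"` or `"ring"`.
#' @param spacing Grid spacing, um.
#' @param margin Wall margin, um; default [recommended_margin()].
#' @param fz_ratio Out-of-plane to in-plane force magnitude ratio (0 = pure
#'   in-plane loading).
#' @return A list of class `tfm_fixture`: `forces`
#'   (a [prescribed_force_field()]), `substrate`, `mask`
#'   (a [cluster_mask()]), and `geometry` (centres, radius).
#' @export
make_two_cell_fixture <- function(diameter = 20, gap = 10, E = 1, nu = 0.45,
                                  thickness = 70, peak_force = 0.5,
                                  pattern = c("contractile_pair", "ring"),
                                  spacing = 4.84, margin = NULL,
                                  fz_ratio = 0) {
  pattern <- match.arg(pattern)
  if (diameter <= 0 || gap <= 0) {
    stop("geometry error: circles must have positive diameter and must not overlap")
  }
  radius <- diameter / 2
  cx <- gap / 2 + radius
  centers <- rbind(c(-cx, 0), c(cx, 0))
  bbox_diag <- sqrt((2 * cx + diameter)^2 + diameter^2)
  if (is.null(margin)) margin <- recommended_margin(thickness, bbox_diag)
  grid <- centred_grid(cx + radius + margin, radius + margin, spacing)
  substrate <- substrate_model(E, nu, thickness,
                               lateral_size_x = (grid$nx - 1) * spacing,
                               lateral_size_y = (grid$ny - 1) * spacing)
  labels <- rasterize_disks(grid, centers, radius)

  xs <- grid_x(grid); ys <- grid_y(grid)
  X <- matrix(xs, grid$nx, grid$ny)
  Y <- matrix(ys, grid$nx, grid$ny, byrow = TRUE)
  fx <- matrix(0, grid$nx, grid$ny)
  fy <- matrix(0, grid$nx, grid$ny)
  for (l in 1:2) {
    sel <- labels == l
    dx <- X - centers[l, 1]; dy <- Y - centers[l, 2]
    if (pattern == "contractile_pair") {
      # both halves pull toward the cell's own centre line
      side <- sign(dx)
      f <- -peak_force * side
      n_l <- sum(sel & side < 0); n_r <- sum(sel & side > 0)
      if (n_r > 0 && n_l > 0) f[side > 0] <- f[side > 0] * (n_l / n_r)
      fx[sel] <- f[sel]
    } else {
      rho <- sqrt(dx^2 + dy^2)
      on <- sel & rho > 0.5 * radius & rho <= radius
      fx[on] <- -peak_force * (dx / rho)[on]
      fy[on] <- -peak_force * (dy / rho)[on]
    }
  }
  bal <- balance_clusters(fx, fy, labels)
  fz <- NULL
  if (fz_ratio > 0) {
    fz <- fz_ratio * sqrt(bal$fx^2 + bal$fy^2) * sign(X - ifelse(X < 0, -cx, cx))
    for (l in 1:2) {       # balance the z-load per cluster as well
      sel <- labels == l & abs(fz) > 0
      if (any(sel)) fz[sel] <- fz[sel] - sum(fz[labels == l]) / sum(sel)
    }
  }
  structure(
    list(
      forces = prescribed_force_field(
        grid, bal$fx, bal$fy, fz, labels,
        metadata = list(generator = "two_cell", diameter = diameter, gap = gap,
                        peak_force = peak_force, pattern = pattern,
                        fz_ratio = fz_ratio, spacing = spacing, margin = margin)
      ),
      substrate = substrate,
      mask = cluster_mask(grid, labels),
      geometry = list(centers = centers, radius = radius)
    ),
    class = "tfm_fixture"
  )
}

#' Single contractile disk fixture
#'
#' One circular cluster whose traction points radially inward with magnitude
#' growing linearly from the centre (`t(rho) = peak_traction * rho / R`),
#' the textbook model of an axisymmetrically contracting cell or cluster.
#' Self-equilibrated by symmetry.  The optional rim taper brings the
#' traction continuously back to zero over the outer `taper` fraction of
#' the radius, giving a truth field that successive mesh refinements can
#' actually resolve (used by the mesh-convergence study).
#'
#' @param radius Cluster radius, um.
#' @param center `c(x, y)` of the cluster centre, um.
#' @param peak_traction Traction magnitude at the rim, kPa.
#' @param E,nu,thickness Substrate material and geometry (kPa / - / um).
#' @param spacing Grid spacing, um.
#' @param margin Wall margin, um; default [recommended_margin()].
#' @param taper Fraction of the radius over which the traction ramps back
#'   to zero at the rim (0 = sharp edge).
#' @return A `tfm_fixture` list like [make_two_cell_fixture()]'s.
#' @export
make_contractile_disk <- function(radius = 15, center = c(0, 0),
                                  peak_traction = 0.2, E = 1, nu = 0.45,
                                  thickness = 70, spacing = 4.84,
                                  margin = NULL, taper = 0) {
  if (radius <= 0) stop("radius must be positive")
  if (is.null(margin)) margin <- recommended_margin(thickness, 2 * sqrt(2) * radius)
  grid <- centred_grid(abs(center[1]) + radius + margin,
                       abs(center[2]) + radius + margin, spacing)
  substrate <- substrate_model(E, nu, thickness,
                               lateral_size_x = (grid$nx - 1) * spacing,
                               lateral_size_y = (grid$ny - 1) * spacing)
  labels <- rasterize_disks(grid, matrix(center, 1), radius)
  xs <- grid_x(grid); ys <- grid_y(grid)
  dx <- matrix(xs - center[1], grid$nx, grid$ny)
  dy <- matrix(ys - center[2], grid$nx, grid$ny, byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  area <- tributary_areas(grid)
  tmag <- peak_traction * rho / radius
  if (taper > 0) {
    r0 <- (1 - taper) * radius
    ramp <- pmax(0, pmin(1, (radius - rho) / (radius - r0)))
    tmag <- ifelse(rho <= r0, tmag, peak_traction * (r0 / radius) * ramp)
  }
  sel <- labels == 1L & rho > 0
  fx <- matrix(0, grid$nx, grid$ny); fy <- fx
  fx[sel] <- (-tmag * dx / rho * area)[sel]
  fy[sel] <- (-tmag * dy / rho * area)[sel]
  bal <- balance_clusters(fx, fy, labels)
  structure(
    list(
      forces = prescribed_force_field(
        grid, bal$fx, bal$fy, NULL, labels,
        metadata = list(generator = "contractile_disk", radius = radius,
                        center = center, peak_traction = peak_traction,
                        spacing = spacing, margin = margin)
      ),
      substrate = substrate,
      mask = cluster_mask(grid, labels),
      geometry = list(centers = matrix(center, 1), radius = radius)
    ),
    class = "tfm_fixture"
  )
}

#' Forward-solve surface displacements under a prescribed force field
#'
#' The validation workhorse: apply a known force field on the free top
#' surface (zero force elsewhere there), clamp the bottom and the lateral
#' walls, solve, and return the top-surface displacements.  Feeding these
#' displacements back through [recover_mixed()] must reproduce the forces --
#' the round trip that demonstrates uniqueness of the traction solution.
#'
#' @param field A [prescribed_force_field()].
#' @param substrate A [substrate_model()].
#' @param with_z Return the out-of-plane component `uz`?
#' @param context Optional prebuilt [fem_context()].
#' @param options A [fem_solver_options()] (ignored if `context` given).
#' @return A [surface_displacement_field()] on the same grid.
#' @export
forward_surface_displacements <- function(field, substrate, with_z = TRUE,
                                          context = NULL,
                                          options = fem_solver_options()) {
  stopifnot(inherits(field, "prescribed_force_field"))
  ctx <- resolve_context(context, substrate, field$grid, options)
  mesh <- ctx$mesh
  bc <- clamped_base_bc(mesh)
  free_top <- free_surface_nodes(mesh)
  sn <- surface_node_matrix(mesh)
  keep <- match(free_top, sn)          # positions of free top nodes in [i,j] order
  bc <- prescribe_force(bc, node_dof(free_top, 1), field$fx[keep])
  bc <- prescribe_force(bc, node_dof(free_top, 2), field$fy[keep])
  bc <- prescribe_force(bc, node_dof(free_top, 3),
                        if (is.null(field$fz)) 0 else field$fz[keep])
  sol <- solve_mbvp(ctx$K, bc, ctx$options, ctx$cache)
  ux <- matrix(sol$u[node_dof(sn, 1)], mesh$nx, mesh$ny)
  uy <- matrix(sol$u[node_dof(sn, 2)], mesh$nx, mesh$ny)
  uz <- if (with_z) matrix(sol$u[node_dof(sn, 3)], mesh$nx, mesh$ny) else NULL
  surface_displacement_field(field$grid, ux, uy, uz)
}

#' Add Gaussian measurement noise to a displacement field
#'
#' Independent zero-mean Gaussian noise per node and component, emulating
#' DIC measurement error.  Reproducible given the seed.
#'
#' @param disp A [surface_displacement_field()].
#' @param sigma Noise standard deviation, um.
#' @param seed Integer seed (mandatory: stochastic generators are always
#'   seeded).
#' @return The noisy [surface_displacement_field()].
#' @export
add_displacement_noise <- function(disp, sigma, seed) {
  stopifnot(inherits(disp, "surface_displacement_field"))
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(disp)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(disp$ux)
  disp$ux <- disp$ux + matrix(stats::rnorm(n, 0, sigma), nrow(disp$ux))
  disp$uy <- disp$uy + matrix(stats::rnorm(n, 0, sigma), nrow(disp$uy))
  if (!is.null(disp$uz)) {
    disp$uz <- disp$uz + matrix(stats::rnorm(n, 0, sigma), nrow(disp$uz))
  }
  disp
}

#' Half-space surface displacement under a tangential point force
#'
#' The Cerruti closed form for a point force tangential to the surface of a
#' semi-infinite elastic half-space -- the kernel classical traction force
#' microscopy builds on, used here as an analytic oracle in the
#' deep-substrate limit.  Along the force axis
#' `u = F (1 + nu) / (pi E r)`; perpendicular to it
#' `u = F (1 + nu)(1 - nu) / (pi E r)`.
#'
#' @param F Force magnitude, nN.
#' @param E Young's modulus, kPa.
#' @param nu Poisson's ratio.
#' @param r Surface distance from the load point, um (> 0).
#' @param direction `"parallel"` (along the force axis) or
#'   `"perpendicular"`.
#' @return Displacement component along the force direction, um.
#' @export
cerruti_surface_displacement <- function(F, E, nu, r,
                                         direction = c("parallel", "perpendicular")) {
  direction <- match.arg(direction)
  if (any(r <= 0)) stop("singularity: the Cerruti solution diverges at r = 0")
  base <- F * (1 + nu) / (pi * E * r)
  if (direction == "parallel") base else base * (1 - nu)
}

#' Deep-substrate benchmark against the Cerruti solution
#'
#' Applies a tangential point load to a substrate much deeper and wider
#' than the observation region and compares the finite-element surface
#' displacement along the force axis with the half-space closed form.  The
#' load problem has two exact mirror symmetries (the in-line displacement is
#' even in both x and y), so one quarter of the domain is solved with
#' symmetry boundary conditions (`uy = uz = 0` on the x = 0 plane, `uy = 0`
#' on the y = 0 plane, a quarter of the load at the corner), which makes the
#' wide domain affordable.
#'
#' @param spacing Grid spacing h, um (also the vertical spacing).
#' @param force Load magnitude, nN.
#' @param nu Poisson's ratio.
#' @param E Young's modulus, kPa.
#' @param lateral_factor Wall distance in units of h.
#' @param depth_factor Substrate thickness in units of h.
#' @param radii_factors Observation radii in units of h.
#' @param options A [fem_solver_options()].
#' @return Data frame with columns `r_um`, `u_fem_um`, `u_cerruti_um`,
#'   `rel_error`.
#' @export
deep_substrate_benchmark <- function(spacing = 2, force = 1, nu = 0.45, E = 1,
                                     lateral_factor = 48, depth_factor = 60,
                                     radii_factors = 3:6,
                                     options = fem_solver_options()) {
  h <- spacing
  nx <- lateral_factor + 1L
  nz <- depth_factor + 1L
  if (max(radii_factors) * 10 > depth_factor) {
    stop("substrate depth must be at least 10x the largest observation radius")
  }
  mesh <- hex_mesh(nx, nx, nz, c(h, h, h), origin = c(0, 0))
  substrate <- substrate_model(E, nu, depth_factor * h)
  # fully integrated element: at nu = 0.45 locking is mild, and the
  # near-singular point-load field is cleaner without the volumetric
  # under-integration's pressure modes
  K <- assemble_global(mesh, substrate, integration = "full")
  idx <- array(FALSE, c(nx, nx, nz))
  idx[, , 1] <- TRUE; idx[nx, , ] <- TRUE; idx[, nx, ] <- TRUE
  fixed <- which(idx)
  bc <- mixed_bc_set(nrow(K))
  bc <- prescribe_displacement(
    bc, node_dof(rep(fixed, each = 3L), rep(1:3, length(fixed))), 0)
  idx[] <- FALSE; idx[1, , ] <- TRUE
  p_x0 <- setdiff(which(idx), fixed)
  idx[] <- FALSE; idx[, 1, ] <- TRUE
  p_y0 <- setdiff(which(idx), c(fixed, p_x0))
  bc <- prescribe_displacement(bc, node_dof(p_x0, 2), 0)
  bc <- prescribe_displacement(bc, node_dof(p_x0, 3), 0)
  bc <- prescribe_displacement(bc, node_dof(p_y0, 2), 0)
  bc <- prescribe_force(bc, node_dof(node_index(mesh, 1, 1, nz), 1), force / 4)
  sol <- solve_mbvp(K, bc, options)
  r_um <- radii_factors * h
  u_fem <- vapply(radii_factors, function(m) {
    sol$u[node_dof(node_index(mesh, 1L + m, 1L, nz), 1)]
  }, 0)
  u_cer <- cerruti_surface_displacement(force, E, nu, r_um, "parallel")
  data.frame(r_um = r_um, u_fem_um = u_fem, u_cerruti_um = u_cer,
             rel_error = u_fem / u_cer - 1)
}
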