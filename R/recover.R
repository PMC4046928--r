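#' Recover cell traction by the mixed boundary-condition scheme
#'
#' The core of the method.  Measured displacements are prescribed only at
#' the surface nodes under the cells; every node outside the cell boundaries
#' carries the exact traction-free condition (zero force) instead, so its
#' displacement never needs to be measured.  Bottom and lateral walls are
#' clamped.  The nodal reactions at the displacement-prescribed nodes are
#' the cell's nodal forces; divided by the tributary areas they give the
#' traction.  No regularization is involved: with the force support covered
#' by the mask, the solution of the mixed problem is unique.
#'
#' If `disp` lacks `uz` (2D imaging), the out-of-plane condition `Fz = 0`
#' is prescribed at the labelled nodes instead and only in-plane traction is
#' returned.  That shortcut is accurate only when the gel is nearly
#' incompressible (in-plane and out-of-plane responses decouple as the
#' Poisson ratio approaches 0.5), so it is accepted for `nu >= 0.4` and
#' refused otherwise.
#'
#' @param disp A [surface_displacement_field()].
#' @param mask A [cluster_mask()] on the same grid.
#' @param substrate A [substrate_model()].
#' @param smooth_sigma Optional Gaussian pre-smoothing of the displacement
#'   field, in grid units; 0 (default) disables it.
#' @param nu_check Refuse in-plane-only input when `nu < 0.4` (default).
#'   The Poisson-decoupling study disables this to *measure* the error the
#'   guard protects against.
#' @param context Optional prebuilt [fem_context()].
#' @param options A [fem_solver_options()] (ignored if `context` given).
#' @return A list with elements `traction` (a [traction_field()]) and
#'   `report` (a `recovery_report`: per-cluster error ratio and net force,
#'   RMS traction, solver residual).
#' @export
recover_mixed <- function(disp, mask, substrate, smooth_sigma = 0,
                          nu_check = TRUE,
                          context = NULL, options = fem_solver_options()) {
  check_recovery_inputs(disp, mask, substrate, need_full_field = FALSE)
  in_plane <- !has_uz(disp)
  if (in_plane && nu_check) check_in_plane_ok(substrate)
  if (smooth_sigma > 0) disp <- smooth_displacement_field(disp, smooth_sigma)
  ctx <- resolve_context(context, substrate, disp$grid, options)
  mesh <- ctx$mesh

  bc <- clamped_base_bc(mesh)
  sn <- surface_node_matrix(mesh)
  lab_pos <- which(mask$labels > 0L)          # positions in [i, j] order
  lab_nodes <- sn[lab_pos]
  bc <- prescribe_displacement(bc, node_dof(lab_nodes, 1), disp$ux[lab_pos])
  bc <- prescribe_displacement(bc, node_dof(lab_nodes, 2), disp$uy[lab_pos])
  if (!in_plane) {
    bc <- prescribe_displacement(bc, node_dof(lab_nodes, 3), disp$uz[lab_pos])
  }
  # all remaining free-surface DOFs already carry the zero-force default,
  # which is exactly the traction-free condition (and Fz = 0 under the
  # cells in in-plane mode)
  sol <- solve_mbvp(ctx$K, bc, ctx$options, ctx$cache)

  traction_from_reactions(sol, mesh, mask, in_plane, iterations = NULL,
                          history = NULL)
}

#' Recover traction by the iterative whole-field displacement scheme
#'
#' The traditional alternative: prescribe the measured in-plane
#' displacements at every surface node (intra- and extracellular), then
#' iterate to enforce the traction-free condition outside the cells:
#' solve for the nodal forces, zero all extracellular forces, forward-solve
#' a corrected displacement field, restore the measured displacements under
#' the cells while keeping the computed extracellular ones, and repeat until
#' the RMS of the surface nodal forces changes by less than `rms_tol`
#' between cycles.  `Fz = 0` is prescribed at every surface node throughout
#' (the measured field is in-plane).
#'
#' @param disp A [surface_displacement_field()], valid on the whole grid --
#'   unlike the mixed scheme, this one needs the extracellular data.
#' @param mask A [cluster_mask()] on the same grid.
#' @param substrate A [substrate_model()].
#' @param rms_tol Convergence threshold on the relative change of the RMS
#'   surface nodal force between consecutive cycles (default 0.05).
#' @param max_iter Cycle cap; exceeding it is an error carrying the history.
#' @param context Optional prebuilt [fem_context()].
#' @param options A [fem_solver_options()] (ignored if `context` given).
#' @return As [recover_mixed()]; the report additionally carries
#'   `iterations` and the per-cycle RMS `history`.
#' @export
recover_whole_field_iterative <- function(disp, mask, substrate,
                                          rms_tol = 0.05, max_iter = 50L,
                                          context = NULL,
                                          options = fem_solver_options()) {
  check_recovery_inputs(disp, mask, substrate, need_full_field = TRUE)
  check_in_plane_ok(substrate)
  ctx <- resolve_context(context, substrate, disp$grid, options)
  mesh <- ctx$mesh
  sn <- surface_node_matrix(mesh)
  free_top <- free_surface_nodes(mesh)
  top_pos <- match(free_top, sn)
  lab_free <- mask$labels[top_pos] > 0L        # labelled among free top nodes

  ux <- disp$ux[top_pos]
  uy <- disp$uy[top_pos]
  rms_history <- numeric(0)
  forces <- NULL
  converged <- FALSE

  for (cycle in seq_len(max_iter)) {
    # (b) displacement half-cycle: prescribe (ux, uy) at every free top
    # node, Fz = 0 there; solve for the nodal forces
    bc <- clamped_base_bc(mesh)
    bc <- prescribe_displacement(bc, node_dof(free_top, 1), ux)
    bc <- prescribe_displacement(bc, node_dof(free_top, 2), uy)
    sol <- solve_mbvp(ctx$K, bc, ctx$options, ctx$cache)
    fx <- sol$reactions[node_dof(free_top, 1)]
    fy <- sol$reactions[node_dof(free_top, 2)]
    # enforce the traction-free condition outside the cells
    fx[!lab_free] <- 0
    fy[!lab_free] <- 0
    rms <- sqrt(mean(fx^2 + fy^2))
    rms_history <- c(rms_history, rms)
    forces <- list(fx = fx, fy = fy)
    if (rms == 0 ||
        (cycle > 1L && abs(rms - rms_history[cycle - 1L]) <
           rms_tol * rms_history[cycle - 1L])) {
      converged <- TRUE
      break
    }
    if (cycle == max_iter) break
    # (c) force half-cycle: forward-solve displacements from the cleaned
    # force field
    bc2 <- clamped_base_bc(mesh)
    bc2 <- prescribe_force(bc2, node_dof(free_top, 1), fx)
    bc2 <- prescribe_force(bc2, node_dof(free_top, 2), fy)
    sol2 <- solve_mbvp(ctx$K, bc2, ctx$options, ctx$cache)
    # (d) restore measured displacements under the cells, keep computed
    # extracellular displacements
    ux_new <- sol2$u[node_dof(free_top, 1)]
    uy_new <- sol2$u[node_dof(free_top, 2)]
    ux_new[lab_free] <- disp$ux[top_pos][lab_free]
    uy_new[lab_free] <- disp$uy[top_pos][lab_free]
    ux <- ux_new
    uy <- uy_new
  }
  if (!converged) {
    cond <- structure(
      class = c("tfm_no_convergence", "error", "condition"),
      list(message = paste0("whole-field iteration did not converge within ",
                            max_iter, " cycles (last relative RMS change ",
                            signif(abs(diff(utils::tail(rms_history, 2))) /
                                     rms_history[length(rms_history) - 1L], 3), ")"),
           call = sys.call(-1), history = rms_history))
    stop(cond)
  }

  fsol <- list(reactions = numeric(3 * mesh_n_nodes(mesh)),
               residual = sol$residual)
  fsol$reactions[node_dof(free_top, 1)] <- forces$fx
  fsol$reactions[node_dof(free_top, 2)] <- forces$fy
  traction_from_reactions(fsol, mesh, mask, in_plane = TRUE,
                          iterations = length(rms_history),
                          history = rms_history)
}

# In-plane-only data can stand in for the full 3D field only near the
# incompressible limit, where in-plane and out-of-plane responses decouple.
check_in_plane_ok <- function(substrate) {
  if (substrate$poissons_ratio < 0.4) {
    stop("in-plane displacements alone cannot determine the traction at ",
         "Poisson's ratio ", substrate$poissons_ratio, " (< 0.4): the ",
         "out-of-plane component must be measured and supplied as `uz`")
  }
  invisible()
}

# Shared validation for both recovery schemes.
check_recovery_inputs <- function(disp, mask, substrate, need_full_field) {
  stopifnot(inherits(disp, "surface_displacement_field"),
            inherits(mask, "cluster_mask"),
            inherits(substrate, "substrate_model"))
  if (!grids_identical(disp$grid, mask$grid)) {
    stop("displacement field and mask are on different grids")
  }
  lab <- mask$labels > 0L
  if (need_full_field) {
    if (any(!disp$valid)) {
      bad <- which(!disp$valid, arr.ind = TRUE)[1, ]
      stop("the whole-field scheme needs valid displacements at every ",
           "surface node; node (i=", bad[1], ", j=", bad[2], ") is invalid")
    }
  } else if (any(lab & !disp$valid)) {
    bad <- which(lab & !disp$valid, arr.ind = TRUE)[1, ]
    stop("labelled node (i=", bad[1], ", j=", bad[2],
         ") has no valid displacement data")
  }
  # labelled nodes on (or one node away from) the clamped walls make the
  # problem ill-posed: the wall prescription wins and the traction there is
  # meaningless
  nx <- mask$grid$nx; ny <- mask$grid$ny
  ii <- matrix(seq_len(nx), nx, ny)
  jj <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ring <- ii <= 2L | ii >= nx - 1L | jj <= 2L | jj >= ny - 1L
  if (any(lab & ring)) {
    stop("geometry error: the mask touches the lateral wall margin; ",
         "enlarge the modelled domain")
  }
  # softer check: warn when the walls are closer than the recommended margin
  xs <- grid_x(mask$grid); ys <- grid_y(mask$grid)
  li <- which(lab, arr.ind = TRUE)
  if (nrow(li) > 0) {
    dwall <- min(xs[li[, 1]] - xs[1], xs[nx] - xs[li[, 1]],
                 ys[li[, 2]] - ys[1], ys[ny] - ys[li[, 2]])
    bbox <- sqrt(diff(range(xs[li[, 1]]))^2 + diff(range(ys[li[, 2]]))^2)
    rec <- recommended_margin(substrate$thickness, bbox)
    if (dwall < 0.5 * rec) {
      warning("labelled nodes are ", signif(dwall, 3),
              " um from the clamped walls; less than half the recommended margin (",
              signif(rec, 3), " um) -- recovered traction may be distorted")
    }
  }
  invisible()
}

# Build the traction field + report from reactions at surface nodes.
traction_from_reactions <- function(sol, mesh, mask, in_plane, iterations,
                                    history) {
  grid <- mask$grid
  sn <- surface_node_matrix(mesh)
  fx <- matrix(sol$reactions[node_dof(sn, 1)], mesh$nx, mesh$ny)
  fy <- matrix(sol$reactions[node_dof(sn, 2)], mesh$nx, mesh$ny)
  fz <- if (in_plane) NULL else matrix(sol$reactions[node_dof(sn, 3)],
                                       mesh$nx, mesh$ny)
  # wall-ring reactions are clamp reactions, not cell traction
  lab <- mask$labels > 0L
  fx[!lab] <- 0; fy[!lab] <- 0
  if (!is.null(fz)) fz[!lab] <- 0
  area <- tributary_areas(grid)
  tf <- traction_field(grid, tx = fx / area, ty = fy / area,
                       tz = if (is.null(fz)) NULL else fz / area,
                       labels = mask$labels)
  report <- recovery_report(tf, residual = sol$residual,
                            iterations = iterations, history = history)
  list(traction = tf, report = report)
}

#' Summarize a recovered traction field
#'
#' @param tf A [traction_field()].
#' @param residual Solver residual to record.
#' @param iterations,history Iteration count and RMS history (iterative
#'   scheme only).
#' @return A `recovery_report`: data frame `clusters` (id, node count, error
#'   ratio, net force components and magnitude, nN), `rms_traction` (kPa,
#'   over labelled nodes), `residual`, `iterations`, `history`.
#' @export
recovery_report <- function(tf, residual = NA_real_, iterations = NULL,
                            history = NULL) {
  ids <- cluster_ids(tf)
  clusters <- do.call(rbind, lapply(ids, function(l) {
    sel <- tf$labels == l
    nfx <- sum(tf$fx[sel]); nfy <- sum(tf$fy[sel])
    # a zero-force cluster has undefined eps; NA in the table suffices
    data.frame(cluster = l, n_nodes = sum(sel),
               error_ratio = suppressWarnings(error_ratio(tf, l)),
               net_fx = nfx, net_fy = nfy,
               net_force = sqrt(nfx^2 + nfy^2))
  }))
  lab <- tf$labels > 0L
  rms_traction <- if (any(lab)) sqrt(mean(traction_magnitude(tf)[lab]^2)) else 0
  structure(
    list(clusters = clusters, rms_traction = rms_traction,
         residual = residual, iterations = iterations, history = history),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>  RMS traction:", signif(x$rms_traction, 4), "kPa")
  if (!is.null(x$iterations)) cat(",", x$iterations, "iteration(s)")
  cat("\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Error ratio of a cluster's recovered forces
#'
#' The self-equilibration diagnostic: every isolated cell or cluster exerts
#' zero net force on its substrate, so the magnitude of the net in-plane
#' nodal force divided by the sum of the nodal force magnitudes,
#' `eps = |sum_i (F_xi, F_yi)| / sum_i |(F_xi, F_yi)|`,
#' is 0 for an exact solution and 1 for a fully unbalanced one.
#'
#' @param tf A [traction_field()].
#' @param cluster_id Cluster label to evaluate.
#' @return `eps` in `[0, 1]`, or `NA` (with a warning) if the cluster
#'   carries no force at all.
#' @export
error_ratio <- function(tf, cluster_id) {
  stopifnot(inherits(tf, "traction_field"))
  sel <- tf$labels == cluster_id
  if (!any(sel)) stop("cluster ", cluster_id, " not present in the field")
  mags <- sqrt(tf$fx[sel]^2 + tf$fy[sel]^2)
  denom <- sum(mags)
  if (denom == 0) {
    warning("cluster ", cluster_id, " carries zero force; error ratio undefined")
    return(NA_real_)
  }
  sqrt(sum(tf$fx[sel])^2 + sum(tf$fy[sel])^2) / denom
}

#' Net force vector of a cluster
#'
#' @param tf A [traction_field()].
#' @param cluster_id Cluster label.
#' @return Named vector `c(fx, fy[, fz])`, nN.
#' @export
cluster_net_force <- function(tf, cluster_id) {
  stopifnot(inherits(tf, "traction_field"))
  sel <- tf$labels == cluster_id
  if (!any(sel)) stop("cluster ", cluster_id, " not present in the field")
  out <- c(fx = sum(tf$fx[sel]), fy = sum(tf$fy[sel]))
  if (!is.null(tf$fz)) out <- c(out, fz = sum(tf$fz[sel]))
  out
}

#' RMS node-by-node difference between two traction fields
#'
#' Root mean square of the vector differences over the nodes of a region,
#' reported for traction (kPa) and nodal force (nN) separately.  The
#' comparison metric used to judge agreement between recovery schemes,
#' meshes, or region choices.
#'
#' @param tf_a,tf_b [traction_field()]s on the same grid.
#' @param region A [cluster_mask()]; nodes with label > 0 enter the RMS.
#' @return Named vector `c(rms_traction, rms_force)`.
#' @export
rms_difference <- function(tf_a, tf_b, region) {
  stopifnot(inherits(tf_a, "traction_field"), inherits(tf_b, "traction_field"),
            inherits(region, "cluster_mask"))
  if (!grids_identical(tf_a$grid, tf_b$grid) ||
      !grids_identical(tf_a$grid, region$grid)) {
    stop("alignment error: traction fields and region are on different grids")
  }
  sel <- region$labels > 0L
  dt2 <- (tf_a$tx - tf_b$tx)[sel]^2 + (tf_a$ty - tf_b$ty)[sel]^2
  df2 <- (tf_a$fx - tf_b$fx)[sel]^2 + (tf_a$fy - tf_b$fy)[sel]^2
  if (!is.null(tf_a$tz) && !is.null(tf_b$tz)) {
    dt2 <- dt2 + (tf_a$tz - tf_b$tz)[sel]^2
    df2 <- df2 + (tf_a$fz - tf_b$fz)[sel]^2
  }
  c(rms_traction = sqrt(mean(dt2)), rms_force = sqrt(mean(df2)))
}

# Gaussian smoothing of the displacement components (optional denoising;
# off by default everywhere).
smooth_displacement_field <- function(disp, sigma) {
  smooth1 <- function(m) {
    half <- max(1L, ceiling(3 * sigma))
    kern <- stats::dnorm(-half:half, sd = sigma)
    kern <- kern / sum(kern)
    # separable convolution with edge renormalization
    pad_apply <- function(mat) {
      out <- mat * 0
      wgt <- mat * 0
      for (o in -half:half) {
        src <- pmin(pmax(seq_len(nrow(mat)) + o, 1L), nrow(mat))
        out <- out + kern[o + half + 1L] * mat[src, , drop = FALSE]
      }
      out
    }
    t(pad_apply(t(pad_apply(m))))
  }
  disp$ux <- smooth1(disp$ux)
  disp$uy <- smooth1(disp$uy)
  if (!is.null(disp$uz)) disp$uz <- smooth1(disp$uz)
  disp
}

#' Grow a cluster mask outward
#'
#' Morphological dilation by `rings` node rings; newly added nodes take the
#' label of the nearest labelled node (ties to the lower label).  Used to
#' emulate a generously drawn cell boundary.
#'
#' @param mask A [cluster_mask()].
#' @param rings Number of rings to add (>= 0).
#' @return The enlarged [cluster_mask()].
#' @export
enlarge_mask <- function(mask, rings = 1L) {
  stopifnot(inherits(mask, "cluster_mask"))
  lab <- mask$labels
  nx <- nrow(lab); ny <- ncol(lab)
  for (r in seq_len(rings)) {
    new <- lab
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      shifted <- matrix(0L, nx, ny)
      si <- seq_len(nx) - sh[1]; sj <- seq_len(ny) - sh[2]
      ok_i <- si >= 1 & si <= nx; ok_j <- sj >= 1 & sj <= ny
      shifted[ok_i, ok_j] <- lab[si[ok_i], sj[ok_j]]
      take <- new == 0L & shifted > 0L
      new[take] <- shifted[take]
      upgrade <- new > 0L & shifted > 0L & shifted < new & lab == 0L
      new[upgrade] <- shifted[upgrade]
    }
    lab <- new
  }
  cluster_mask(mask$grid, lab)
}

#' Bounding-box mask around all labelled nodes
#'
#' A single rectangular region (label 1) covering every labelled node plus
#' a padding ring -- the "larger area enclosing both the cells" style of
#' region choice.
#'
#' @param mask A [cluster_mask()].
#' @param pad Padding in nodes around the bounding box.
#' @return A [cluster_mask()] with one rectangular cluster.
#' @export
bounding_box_mask <- function(mask, pad = 0L) {
  stopifnot(inherits(mask, "cluster_mask"))
  idx <- which(mask$labels > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no labelled nodes")
  i_rng <- range(idx[, 1]) + c(-pad, pad)
  j_rng <- range(idx[, 2]) + c(-pad, pad)
  i_rng <- pmin(pmax(i_rng, 1L), mask$grid$nx)
  j_rng <- pmin(pmax(j_rng, 1L), mask$grid$ny)
  lab <- matrix(0L, mask$grid$nx, mask$grid$ny)
  lab[i_rng[1]:i_rng[2], j_rng[1]:j_rng[2]] <- 1L
  cluster_mask(mask$grid, lab)
}
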