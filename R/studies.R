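#' Mesh-size convergence study
#'
#' Recovers the traction of one fixture at several grid spacings and
#' quantifies how much the answer still moves between successive
#' refinements.  The displacement field is generated once on the finest
#' grid by the forward simulator and bilinearly resampled onto each coarser
#' recovery grid (one measured field, several analysis meshes); the
#' recovered traction of each mesh is interpolated back onto the finest
#' grid over the true cluster region for the pairwise comparison.
#'
#' @param fixture A `tfm_fixture` built at the finest spacing, e.g.
#'   `make_two_cell_fixture(spacing = min(spacings))`.
#' @param spacings Decreasing grid spacings, um; the last must equal the
#'   fixture's spacing.  A spacing above 20% of the cluster size draws a
#'   warning (too coarse to resolve cell-scale traction gradients).
#' @param context Optional [fem_context()] for the fixture's own grid.
#' @param options A [fem_solver_options()].
#' @return A `study_result` list: `table` (one row per spacing: spacing,
#'   per-cluster error ratios, RMS traction), `pairwise` (successive RMS
#'   traction differences on the reference grid, kPa), `provenance`.
#' @export
mesh_convergence_study <- function(fixture, spacings = c(6.45, 4.84, 3.23),
                                   context = NULL,
                                   options = fem_solver_options()) {
  stopifnot(inherits(fixture, "tfm_fixture"))
  if (length(spacings) < 1L) stop("need at least one spacing")
  if (is.unsorted(rev(spacings), strictly = TRUE) && length(spacings) > 1L) {
    stop("`spacings` must be strictly decreasing")
  }
  ref_grid <- fixture$forces$grid
  if (abs(min(spacings) - ref_grid$spacing[1]) > 1e-9) {
    stop("the fixture must be built at the finest spacing (",
         min(spacings), " um)")
  }
  cell_size <- 2 * fixture$geometry$radius
  if (max(spacings) > 0.2 * cell_size) {
    warning("coarsest spacing ", max(spacings), " um exceeds 20% of the ",
            "cluster size (", cell_size, " um); expect poorly resolved traction")
  }
  substrate <- fixture$substrate
  # one "measured" displacement field, on the finest grid
  ref_ctx <- resolve_context(context, substrate, ref_grid, options)
  disp_ref <- forward_surface_displacements(fixture$forces, substrate,
                                            with_z = FALSE, context = ref_ctx)
  ids <- cluster_ids(fixture$mask)
  ref_lab <- which(fixture$mask$labels > 0L, arr.ind = TRUE)
  ref_xy <- cbind(grid_x(ref_grid)[ref_lab[, 1]], grid_y(ref_grid)[ref_lab[, 2]])

  rows <- list(); recovered_on_ref <- list()
  for (s in spacings) {
    sub_s <- substrate
    if (abs(s - ref_grid$spacing[1]) < 1e-9) {
      grid_s <- ref_grid
      ctx_s <- ref_ctx
      disp_s <- disp_ref
      mask_s <- fixture$mask
    } else {
      ext <- grid_extent(ref_grid)
      # the coarse analysis grid must stay inside the measured field
      nxs <- as.integer(floor(ext[1] / s + 1e-9)) + 1L
      nys <- as.integer(floor(ext[2] / s + 1e-9)) + 1L
      if (abs((nxs - 1L) * s - ext[1]) > 1e-9 * ext[1] ||
          abs((nys - 1L) * s - ext[2]) > 1e-9 * ext[2]) {
        warning("spacing ", s, " um is not commensurate with the fixture grid; ",
                "displacements are resampled onto a slightly smaller domain")
      }
      grid_s <- surface_grid(nxs, nys, s,
                             origin = c(-(nxs - 1L) * s / 2, -(nys - 1L) * s / 2))
      sub_s <- substrate_model(substrate$youngs_modulus, substrate$poissons_ratio,
                               substrate$thickness)
      ctx_s <- fem_context(sub_s, grid_s, options = options)
      disp_s <- surface_displacement_field(
        grid_s,
        ux = interp_bilinear(disp_ref$ux, ref_grid, grid_s),
        uy = interp_bilinear(disp_ref$uy, ref_grid, grid_s))
      mask_s <- cluster_mask(grid_s, rasterize_disks(grid_s, fixture$geometry$centers,
                                                     fixture$geometry$radius))
    }
    rec <- recover_mixed(disp_s, mask_s, sub_s, context = ctx_s)
    eps <- vapply(ids, function(l) error_ratio(rec$traction, l), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      spacing_um = s, n_nodes = sum(mask_s$labels > 0L),
      rms_traction_kPa = rec$report$rms_traction,
      t(stats::setNames(eps, paste0("eps_cluster_", ids))))
    # recovered traction at the true-cluster reference points
    recovered_on_ref[[as.character(s)]] <- cbind(
      interp_bilinear_at(rec$traction$tx, grid_s, ref_xy),
      interp_bilinear_at(rec$traction$ty, grid_s, ref_xy))
  }
  pairwise <- NULL
  if (length(spacings) > 1L) {
    pairwise <- data.frame(
      from_um = spacings[-length(spacings)], to_um = spacings[-1],
      rms_diff_kPa = vapply(seq_len(length(spacings) - 1L), function(i) {
        a <- recovered_on_ref[[as.character(spacings[i])]]
        b <- recovered_on_ref[[as.character(spacings[i + 1L])]]
        sqrt(mean(rowSums((a - b)^2)))
      }, 0))
  }
  study_result("mesh_convergence", do.call(rbind, rows), pairwise = pairwise,
               provenance = list(fixture = fixture$forces$metadata,
                                 spacings = spacings))
}

#' Poisson-ratio decoupling study
#'
#' How well can in-plane traction be recovered from in-plane displacements
#' alone (prescribing `Fz = 0`) when the cells also push or pull
#' out-of-plane?  For each Poisson ratio, a two-cell fixture carrying an
#' out-of-plane force of `fz_ratio` times the in-plane magnitude at every
#' loaded node is forward-solved in 3D; recovery then sees only (ux, uy).
#' Reported per nu: the relative error of the integrated in-plane force of
#' each loaded half-cell (max over the four poles -- the quantity that
#' matters for a cell's contractile force) and the node-level L2 error of
#' the in-plane force field.  Theory says both shrink as nu approaches 0.5,
#' where in-plane and out-of-plane responses decouple exactly.
#'
#' @param nu_values Poisson ratios in `[0, 0.49]`.
#' @param fz_ratio Out-of-plane to in-plane force magnitude ratio `k`
#'   (`|Fz| = k |F_inplane|` at each loaded node).
#' @param fixture_args Extra arguments passed to [make_two_cell_fixture()]
#'   (e.g. a smaller geometry for quick runs).
#' @param options A [fem_solver_options()].
#' @return A `study_result` with one row per nu: `pole_force_error`
#'   (dimensionless) and `node_l2_error`.
#' @export
poisson_decoupling_study <- function(nu_values = c(0.3, 0.45, 0.49),
                                     fz_ratio = 1, fixture_args = list(),
                                     options = fem_solver_options()) {
  if (any(nu_values < 0 | nu_values > 0.49)) {
    stop("nu values must lie in [0, 0.49]")
  }
  if (fz_ratio < 0) stop("`fz_ratio` must be >= 0")
  rows <- lapply(nu_values, function(nu) {
    fx <- do.call(make_two_cell_fixture,
                  c(list(nu = nu, fz_ratio = fz_ratio), fixture_args))
    ctx <- fem_context(fx$substrate, fx$forces$grid, options = options)
    disp <- forward_surface_displacements(fx$forces, fx$substrate,
                                          with_z = FALSE, context = ctx)
    # nu_check off: quantifying the low-nu error is the point of the sweep
    rec <- recover_mixed(disp, fx$mask, fx$substrate, nu_check = FALSE,
                         context = ctx)
    err <- in_plane_force_errors(rec$traction, fx)
    data.frame(nu = nu, fz_ratio = fz_ratio,
               pole_force_error = err["pole"], node_l2_error = err["node_l2"])
  })
  study_result("poisson_decoupling", do.call(rbind, rows),
               provenance = list(nu_values = nu_values, fz_ratio = fz_ratio,
                                 fixture_args = fixture_args))
}

# Error of recovered in-plane forces against a fixture's prescribed ones:
# "pole" = max relative error of the summed in-plane force over each
# coherent half-cell (split at the cell centre along x), "node_l2" =
# aggregate node-level L2 ratio.
in_plane_force_errors <- function(tf, fixture) {
  truth <- fixture$forces
  lab <- fixture$mask$labels
  X <- matrix(grid_x(truth$grid), truth$grid$nx, truth$grid$ny)
  pole_errs <- c()
  for (l in cluster_ids(fixture$mask)) {
    cx <- fixture$geometry$centers[l, 1]
    for (s in c(-1, 1)) {
      sel <- lab == l & sign(X - cx) == s
      tt <- c(sum(truth$fx[sel]), sum(truth$fy[sel]))
      rr <- c(sum(tf$fx[sel]), sum(tf$fy[sel]))
      nt <- sqrt(sum(tt^2))
      if (nt > 0) pole_errs <- c(pole_errs, sqrt(sum((rr - tt)^2)) / nt)
    }
  }
  sel <- lab > 0L
  num <- sum((tf$fx - truth$fx)[sel]^2 + (tf$fy - truth$fy)[sel]^2)
  den <- sum(truth$fx[sel]^2 + truth$fy[sel]^2)
  c(pole = if (length(pole_errs)) max(pole_errs) else NA_real_,
    node_l2 = sqrt(num / den))
}

#' Region-choice robustness study
#'
#' The mixed scheme needs a mask covering the cells' force support; drawing
#' it generously should not change the answer.  The same displacement field
#' is recovered under the true mask and under an enlarged one, and the
#' node-by-node RMS traction difference inside the true region is reported
#' as a fraction of the peak traction.
#'
#' @param fixture A `tfm_fixture`.
#' @param mask_true A [cluster_mask()]; default the fixture's own.
#' @param mask_enlarged A [cluster_mask()] containing `mask_true` (e.g.
#'   from [enlarge_mask()] or [bounding_box_mask()]).
#' @param context Optional [fem_context()].
#' @param options A [fem_solver_options()].
#' @return A `study_result`: RMS difference (kPa), peak traction (kPa) and
#'   their ratio.
#' @export
region_robustness_study <- function(fixture, mask_true = fixture$mask,
                                    mask_enlarged,
                                    context = NULL,
                                    options = fem_solver_options()) {
  stopifnot(inherits(fixture, "tfm_fixture"))
  if (any(mask_true$labels > 0L & mask_enlarged$labels == 0L)) {
    stop("`mask_enlarged` must contain every labelled node of `mask_true`")
  }
  substrate <- fixture$substrate
  ctx <- resolve_context(context, substrate, fixture$forces$grid, options)
  disp <- forward_surface_displacements(fixture$forces, substrate,
                                        with_z = FALSE, context = ctx)
  rec_true <- recover_mixed(disp, mask_true, substrate, context = ctx)
  rec_enl <- recover_mixed(disp, mask_enlarged, substrate, context = ctx)
  d <- rms_difference(rec_true$traction, rec_enl$traction, mask_true)
  peak <- max(traction_magnitude(rec_true$traction))
  study_result(
    "region_robustness",
    data.frame(rms_diff_kPa = d[["rms_traction"]], peak_traction_kPa = peak,
               rms_diff_over_peak = d[["rms_traction"]] / peak,
               n_true = sum(mask_true$labels > 0L),
               n_enlarged = sum(mask_enlarged$labels > 0L)),
    provenance = list(fixture = fixture$forces$metadata))
}

#' Bundle a study's outputs with its provenance
#'
#' @param study Study name.
#' @param table Main results table (one row per swept value).
#' @param pairwise Optional pairwise-comparison table.
#' @param provenance Named list of inputs that determine the result.
#' @return A list of class `study_result`.
#' @export
study_result <- function(study, table, pairwise = NULL, provenance = list()) {
  provenance$config_hash <- rlang::hash(provenance)
  structure(list(study = study, table = table, pairwise = pairwise,
                 provenance = provenance),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result:", x$study, ">\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

# Bilinear interpolation of a grid matrix onto another grid / points.
interp_bilinear <- function(m, from_grid, to_grid) {
  xy <- as.matrix(expand.grid(x = grid_x(to_grid), y = grid_y(to_grid)))
  matrix(interp_bilinear_at(m, from_grid, xy), to_grid$nx, to_grid$ny)
}

interp_bilinear_at <- function(m, grid, xy) {
  gx <- (xy[, 1] - grid$origin[1]) / grid$spacing[1]
  gy <- (xy[, 2] - grid$origin[2]) / grid$spacing[2]
  tol <- 1e-6
  if (any(gx < -tol | gx > grid$nx - 1 + tol |
          gy < -tol | gy > grid$ny - 1 + tol)) {
    stop("interpolation point outside the source grid")
  }
  gx <- pmin(pmax(gx, 0), grid$nx - 1)
  gy <- pmin(pmax(gy, 0), grid$ny - 1)
  i0 <- pmin(floor(gx), grid$nx - 2) + 1
  j0 <- pmin(floor(gy), grid$ny - 2) + 1
  fx <- gx - (i0 - 1)
  fy <- gy - (j0 - 1)
  idx <- function(i, j) (j - 1) * grid$nx + i
  m[idx(i0, j0)] * (1 - fx) * (1 - fy) +
    m[idx(i0 + 1, j0)] * fx * (1 - fy) +
    m[idx(i0, j0 + 1)] * (1 - fx) * fy +
    m[idx(i0 + 1, j0 + 1)] * fx * fy
}
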