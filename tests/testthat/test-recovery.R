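test_that("forward + mixed recovery is the identity on nodal forces", {
  fx <- small_fixture()
  rec <- recover_mixed(small_disp(), fx$mask, fx$substrate,
                       context = small_context())
  err <- max_force_error(rec$traction, fx$forces, fx$mask)
  expect_lt(err, 0.01)          # uniqueness: the prescribed field comes back
  expect_lt(err, 1e-8)          # and with a direct solve, to solver precision
  # traction-free region is exactly zero by construction
  outside <- fx$mask$labels == 0L
  expect_true(all(rec$traction$tx[outside] == 0))
  expect_true(all(rec$traction$ty[outside] == 0))
})

test_that("zero displacement recovers zero traction", {
  fx <- small_fixture()
  g <- fx$forces$grid
  z <- matrix(0, g$nx, g$ny)
  d0 <- surface_displacement_field(g, z, z)
  rec <- recover_mixed(d0, fx$mask, fx$substrate, context = small_context())
  expect_true(all(rec$traction$fx == 0) && all(rec$traction$fy == 0))
})

test_that("recovery is linear and superposes", {
  fx_pair <- small_fixture()
  fx_ring <- small_fixture("ring")     # same geometry, different load
  ctx <- small_context()
  d_pair <- small_disp()
  d_ring <- forward_surface_displacements(fx_ring$forces, fx_ring$substrate,
                                          with_z = FALSE, context = ctx)
  rec_pair <- recover_mixed(d_pair, fx_pair$mask, fx_pair$substrate, context = ctx)
  rec_ring <- recover_mixed(d_ring, fx_ring$mask, fx_ring$substrate, context = ctx)
  # doubled displacements -> doubled traction
  d2 <- surface_displacement_field(d_pair$grid, 2 * d_pair$ux, 2 * d_pair$uy)
  rec2 <- recover_mixed(d2, fx_pair$mask, fx_pair$substrate, context = ctx)
  expect_equal(rec2$traction$fx, 2 * rec_pair$traction$fx, tolerance = 1e-9)
  # recovery(A + B) = recovery(A) + recovery(B)
  d_sum <- surface_displacement_field(d_pair$grid, d_pair$ux + d_ring$ux,
                                      d_pair$uy + d_ring$uy)
  rec_sum <- recover_mixed(d_sum, fx_pair$mask, fx_pair$substrate, context = ctx)
  peak <- max(abs(rec_sum$traction$fx))
  expect_lt(max(abs(rec_sum$traction$fx -
                      (rec_pair$traction$fx + rec_ring$traction$fx))),
            1e-8 * peak)
})

test_that("enlarging the mask barely changes the recovered traction", {
  fx <- small_fixture()
  ctx <- small_context()
  ring1 <- region_robustness_study(fx, mask_enlarged = enlarge_mask(fx$mask, 1L),
                                   context = ctx)
  expect_lt(ring1$table$rms_diff_over_peak, 0.02)
  bbox <- region_robustness_study(
    fx, mask_enlarged = bounding_box_mask(fx$mask, pad = 1L), context = ctx)
  expect_lt(bbox$table$rms_diff_over_peak, 0.06)
  expect_error(
    region_robustness_study(fx, mask_true = enlarge_mask(fx$mask, 1L),
                            mask_enlarged = fx$mask, context = ctx),
    "contain")
})

test_that("input validation catches the classic mistakes", {
  fx <- small_fixture()
  g <- fx$forces$grid
  d <- small_disp()
  # labelled node without valid displacement data, named in the error
  d_bad <- d
  pos <- which(fx$mask$labels > 0L, arr.ind = TRUE)[1, ]
  d_bad$valid[pos[1], pos[2]] <- FALSE
  expect_error(recover_mixed(d_bad, fx$mask, fx$substrate, context = small_context()),
               paste0("i=", pos[1]))
  # mask touching the wall margin
  lab_wall <- fx$mask$labels
  lab_wall[2, 5] <- 1L
  expect_error(recover_mixed(d, cluster_mask(g, lab_wall), fx$substrate,
                             context = small_context()),
               "wall margin")
  # in-plane-only data on a compressible gel is refused
  soft <- substrate_model(1, 0.3, 20)
  expect_error(recover_mixed(d, fx$mask, soft), "0.4|uz|out-of-plane")
  # mismatched grids
  other_mask <- cluster_mask(surface_grid(g$nx, g$ny, g$spacing + 1),
                             fx$mask$labels)
  expect_error(recover_mixed(d, other_mask, fx$substrate), "different grids")
})

test_that("in-plane-only recovery is refused below nu 0.4 but allowed above", {
  fx <- small_fixture()
  # nu = 0.45 fixture with in-plane data: works (Fz = 0 mode)
  rec <- recover_mixed(small_disp(), fx$mask, fx$substrate,
                       context = small_context())
  expect_null(rec$traction$tz)
  # full 3D data: tz returned
  d3 <- forward_surface_displacements(fx$forces, fx$substrate, with_z = TRUE,
                                      context = small_context())
  rec3 <- recover_mixed(d3, fx$mask, fx$substrate, context = small_context())
  expect_false(is.null(rec3$traction$tz))
})

test_that("iterative whole-field scheme matches the mixed scheme", {
  fx <- small_fixture()
  ctx <- small_context()
  d <- small_disp()
  mix <- recover_mixed(d, fx$mask, fx$substrate, context = ctx)
  it <- recover_whole_field_iterative(d, fx$mask, fx$substrate, context = ctx)
  expect_lte(it$report$iterations, 50)
  expect_equal(length(it$report$history), it$report$iterations)
  dd <- rms_difference(mix$traction, it$traction, fx$mask)
  peak <- max(force_magnitude(mix$traction))
  expect_lt(dd[["rms_force"]], 0.05 * peak)
  # the traction-free region is cleaned exactly
  expect_true(all(it$traction$fx[fx$mask$labels == 0L] == 0))
})

test_that("iterative scheme converges instantly on a zero field", {
  fx <- small_fixture()
  g <- fx$forces$grid
  z <- matrix(0, g$nx, g$ny)
  d0 <- surface_displacement_field(g, z, z)
  it <- recover_whole_field_iterative(d0, fx$mask, fx$substrate,
                                      context = small_context())
  expect_equal(it$report$iterations, 1L)
  expect_true(all(it$traction$fx == 0))
})

test_that("iterative scheme requires full-field data and reports divergence", {
  fx <- small_fixture()
  d <- small_disp()
  d_bad <- d
  d_bad$valid[1, 1] <- FALSE
  expect_error(
    recover_whole_field_iterative(d_bad, fx$mask, fx$substrate,
                                  context = small_context()),
    "every surface node")
  err <- tryCatch(
    recover_whole_field_iterative(d, fx$mask, fx$substrate, max_iter = 1L,
                                  context = small_context()),
    tfm_no_convergence = function(e) e)
  expect_s3_class(err, "tfm_no_convergence")
  expect_equal(length(err$history), 1L)
})

test_that("recovery tolerates measurement noise gracefully", {
  fx <- small_fixture()
  d <- small_disp()
  peak_u <- max(abs(d$ux), abs(d$uy))
  noisy <- add_displacement_noise(d, 0.05 * peak_u, seed = 1)
  rec <- recover_mixed(noisy, fx$mask, fx$substrate, context = small_context())
  eps <- vapply(cluster_ids(fx$mask), function(l) error_ratio(rec$traction, l), 0)
  expect_true(all(eps <= 0.10))
  # optional pre-smoothing runs and keeps the zero-traction region exact
  rec_s <- recover_mixed(noisy, fx$mask, fx$substrate, smooth_sigma = 1,
                         context = small_context())
  expect_true(all(rec_s$traction$tx[fx$mask$labels == 0L] == 0))
})
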