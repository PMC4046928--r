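ref_img <- generate_bead_image(c(192, 192), 600, 1.5, seed = 7)

test_that("bead image generation is seeded, normalized and additive", {
  expect_identical(ref_img, generate_bead_image(c(192, 192), 600, 1.5, seed = 7))
  expect_false(identical(ref_img,
                         generate_bead_image(c(192, 192), 600, 1.5, seed = 8)))
  expect_true(all(ref_img >= 0 & ref_img <= 1))
  blank <- generate_bead_image(c(64, 64), 0, 1.5, seed = 1)
  expect_true(all(blank == 0))
  means <- vapply(c(50, 200, 800),
                  function(n) mean(generate_bead_image(c(128, 128), n, 1.5, 3)),
                  0)
  expect_true(all(diff(means) > 0))
})

test_that("image warping shifts features by +u", {
  # zero field: identity
  expect_equal(warp_image(ref_img, c(0, 0)), ref_img, tolerance = 1e-12)
  # integer shift: exact copy in the interior
  w <- suppressWarnings(warp_image(ref_img, c(3, -2)))
  interior_i <- 10:180; interior_j <- 10:180
  expect_equal(w[interior_i, interior_j],
               ref_img[interior_i - 3, interior_j + 2], tolerance = 1e-12)
  # composition of two shifts equals the summed shift
  w1 <- suppressWarnings(warp_image(ref_img, c(2, 1)))
  w12 <- suppressWarnings(warp_image(w1, c(1, 2)))
  w3 <- suppressWarnings(warp_image(ref_img, c(3, 3)))
  expect_equal(w12[20:170, 20:170], w3[20:170, 20:170], tolerance = 1e-12)
})

test_that("DIC recovers a rigid shift to subpixel accuracy", {
  def <- suppressWarnings(warp_image(ref_img, c(3, -2)))
  d <- dic_displacement_field(bead_image_pair(ref_img, def, 1),
                              window = 32, step = 16, search = 8)
  expect_true(all(d$valid))
  expect_lt(abs(mean(d$ux) - 3), 0.1)
  expect_lt(abs(mean(d$uy) + 2), 0.1)
  # physical units scale with pixel size
  d2 <- dic_displacement_field(bead_image_pair(ref_img, def, 0.5),
                               window = 32, step = 16, search = 8)
  expect_equal(mean(d2$ux), 0.5 * mean(d$ux), tolerance = 1e-9)
})

test_that("DIC of identical images is zero to subpixel tolerance", {
  d <- dic_displacement_field(bead_image_pair(ref_img, ref_img, 1),
                              window = 32, step = 16, search = 4)
  expect_true(all(d$valid))
  # integer peak is exactly 0; the quadratic subpixel fit may wander by a
  # few hundredths of a pixel on asymmetric bead constellations
  expect_lt(max(abs(d$ux)), 0.05)
  expect_lt(max(abs(d$uy)), 0.05)
})

test_that("DIC resolves a linear shear gradient within 10%", {
  def <- suppressWarnings(
    warp_image(ref_img, function(x, y) list(ux = 0.01 * y, uy = 0 * x)))
  d <- dic_displacement_field(bead_image_pair(ref_img, def, 1),
                              window = 32, step = 16, search = 8)
  ys <- grid_y(d$grid)
  slope <- stats::coef(stats::lm(colMeans(d$ux) ~ ys))[2]
  expect_lt(abs(slope / 0.01 - 1), 0.1)
})

test_that("swapping reference and deformed negates the field", {
  def <- suppressWarnings(warp_image(ref_img, c(2, 3)))
  fwd <- dic_displacement_field(bead_image_pair(ref_img, def, 1), 32, 16, 8)
  bwd <- dic_displacement_field(bead_image_pair(def, ref_img, 1), 32, 16, 8)
  expect_lt(max(abs(fwd$ux + bwd$ux)), 0.2)
  expect_lt(max(abs(fwd$uy + bwd$uy)), 0.2)
})

test_that("DIC input validation", {
  expect_error(dic_displacement_field(bead_image_pair(ref_img, ref_img, 1),
                                      window = 500), "window")
  expect_error(bead_image_pair(ref_img, ref_img[1:10, 1:10], 1), "equal")
  expect_error(bead_image_pair(ref_img, ref_img, 0), "positive")
})
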