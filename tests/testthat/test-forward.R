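test_that("self-equilibrated generators have exactly zero net in-plane force", {
  for (pattern in c("contractile_pair", "ring")) {
    fx <- make_two_cell_fixture(diameter = 12, gap = 6, thickness = 20,
                                spacing = 3, margin = 30, pattern = pattern)
    net <- prescribed_net_forces(fx$forces)
    total <- sum(abs(fx$forces$fx)) + sum(abs(fx$forces$fy))
    expect_gt(total, 0)
    expect_lt(max(abs(net)), 1e-12 * total)
    expect_equal(rownames(net), c("1", "2"))
  }
  disk <- make_contractile_disk(radius = 8, thickness = 20, spacing = 2,
                                margin = 30)
  expect_lt(max(abs(prescribed_net_forces(disk$forces))),
            1e-12 * sum(abs(disk$forces$fx) + abs(disk$forces$fy)))
})

test_that("ring and disk patterns point radially inward", {
  fx <- make_two_cell_fixture(diameter = 12, gap = 6, thickness = 20,
                              spacing = 3, margin = 30, pattern = "ring")
  g <- fx$forces$grid
  X <- matrix(grid_x(g), g$nx, g$ny)
  Y <- matrix(grid_y(g), g$nx, g$ny, byrow = TRUE)
  for (l in 1:2) {
    cx <- fx$geometry$centers[l, 1]
    loaded <- fx$forces$labels == l & (abs(fx$forces$fx) + abs(fx$forces$fy)) > 0
    radial <- (fx$forces$fx * (X - cx) + fx$forces$fy * Y)[loaded]
    expect_true(all(radial < 1e-9))
  }
  disk <- make_contractile_disk(radius = 8, thickness = 20, spacing = 2,
                                margin = 30)
  g2 <- disk$forces$grid
  X2 <- matrix(grid_x(g2), g2$nx, g2$ny)
  loaded <- abs(disk$forces$fx) + abs(disk$forces$fy) > 0
  # mirror symmetry about the centre
  expect_equal(disk$forces$fx, -disk$forces$fx[g2$nx:1, ], tolerance = 1e-12)
  expect_equal(disk$forces$fy, disk$forces$fy[g2$nx:1, ], tolerance = 1e-12)
})

test_that("fixture geometry errors are caught", {
  expect_error(make_two_cell_fixture(diameter = 20, gap = 0), "overlap")
  expect_error(make_two_cell_fixture(diameter = -2), "diameter")
  expect_error(make_contractile_disk(radius = 0), "positive")
})

test_that("forward solves are linear and vanish for zero load", {
  fx <- small_fixture()
  ctx <- small_context()
  zero <- prescribed_force_field(fx$forces$grid,
                                 matrix(0, fx$forces$grid$nx, fx$forces$grid$ny),
                                 matrix(0, fx$forces$grid$nx, fx$forces$grid$ny),
                                 labels = fx$forces$labels)
  d0 <- forward_surface_displacements(zero, fx$substrate, context = ctx)
  expect_true(all(d0$ux == 0) && all(d0$uy == 0) && all(d0$uz == 0))
  d1 <- small_disp(with_z = FALSE)
  scaled <- fx$forces
  scaled$fx <- 2.5 * scaled$fx; scaled$fy <- 2.5 * scaled$fy
  d2 <- forward_surface_displacements(scaled, fx$substrate, with_z = FALSE,
                                      context = ctx)
  expect_equal(d2$ux, 2.5 * d1$ux, tolerance = 1e-9)
  expect_equal(d2$uy, 2.5 * d1$uy, tolerance = 1e-9)
})

test_that("displacement noise is seeded and sized correctly", {
  d <- small_disp()
  expect_identical(add_displacement_noise(d, 0, 1), d)
  n1 <- add_displacement_noise(d, 0.01, 42)
  n2 <- add_displacement_noise(d, 0.01, 42)
  n3 <- add_displacement_noise(d, 0.01, 43)
  expect_identical(n1$ux, n2$ux)
  expect_false(identical(n1$ux, n3$ux))
  expect_equal(sd(n1$ux - d$ux), 0.01, tolerance = 0.15)
  expect_error(add_displacement_noise(d, -1, 1), ">= 0")
})

test_that("the Cerruti closed form has the right structure", {
  # u ~ 1/r
  expect_equal(cerruti_surface_displacement(1, 1, 0.45, 2, "parallel"),
               cerruti_surface_displacement(1, 1, 0.45, 1, "parallel") / 2)
  # algebraic value in the incompressible limit along the force axis:
  # u = F (1 + 1/2) / (pi E r) = 1.5 F / (pi E r)
  expect_equal(cerruti_surface_displacement(2, 3, 0.5, 4, "parallel"),
               1.5 * 2 / (pi * 3 * 4), tolerance = 1e-14)
  # perpendicular response is (1 - nu) times the parallel one
  expect_equal(cerruti_surface_displacement(1, 1, 0.3, 5, "perpendicular"),
               0.7 * cerruti_surface_displacement(1, 1, 0.3, 5, "parallel"),
               tolerance = 1e-14)
  expect_error(cerruti_surface_displacement(1, 1, 0.45, 0), "singular")
})

test_that("finite thickness measurably changes the surface response", {
  # identical cluster-scale forces on a 20 um and a 70 um gel: once the
  # load's extent rivals the gel depth the glass below matters, and a
  # secret half-space implementation would make the two fields coincide
  thin <- make_contractile_disk(radius = 30, thickness = 20, spacing = 4,
                                margin = 30, taper = 0.3)
  thick <- make_contractile_disk(radius = 30, thickness = 70, spacing = 4,
                                 margin = 30, taper = 0.3)
  expect_equal(thin$forces$grid$nx, thick$forces$grid$nx)
  d_thin <- forward_surface_displacements(thin$forces, thin$substrate,
                                          with_z = FALSE)
  d_thick <- forward_surface_displacements(thick$forces, thick$substrate,
                                           with_z = FALSE)
  rel <- sqrt(mean((d_thin$ux - d_thick$ux)^2 + (d_thin$uy - d_thick$uy)^2)) /
    sqrt(mean(d_thick$ux^2 + d_thick$uy^2))
  expect_gt(rel, 0.05)
})

test_that("deep-substrate geometry guard rejects shallow configurations", {
  expect_error(deep_substrate_benchmark(depth_factor = 30, radii_factors = 3:6),
               "10x")
})
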