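grid_small <- surface_grid(5, 4, c(2, 3), origin = c(-4, 0))

test_that("tributary areas tile the surface exactly", {
  a <- tributary_areas(grid_small)
  expect_equal(sum(a), 4 * 2 * 3 * 3)          # (nx-1) sx * (ny-1) sy
  expect_equal(a[1, 1], 2 * 3 / 4)             # corner: quarter cell
  expect_equal(a[1, 2], 2 * 3 / 2)             # edge: half cell
  expect_equal(a[3, 2], 2 * 3)                 # interior: full cell
})

test_that("traction fields keep force = traction x area per node", {
  tx <- matrix(stats::rnorm(20), 5, 4)
  ty <- matrix(stats::rnorm(20), 5, 4)
  lab <- matrix(1L, 5, 4)
  tf <- traction_field(grid_small, tx, ty, labels = lab)
  expect_equal(tf$fx, tx * tf$area)
  expect_equal(tf$fy, ty * tf$area)
  expect_null(tf$fz)
})

test_that("error ratio is 0 for a dipole, 1 for a single force, NA when empty", {
  lab <- matrix(0L, 5, 4)
  lab[2:3, 2] <- 1L
  lab[5, 4] <- 2L
  lab[1, 4] <- 3L
  tx <- matrix(0, 5, 4); ty <- matrix(0, 5, 4)
  a <- tributary_areas(grid_small)
  tx[2, 2] <- 1 / a[2, 2]; tx[3, 2] <- -1 / a[3, 2]   # perfect dipole
  ty[5, 4] <- 2 / a[5, 4]                              # lone y-directed force
  tf <- traction_field(grid_small, tx, ty, labels = lab)
  expect_equal(error_ratio(tf, 1L), 0)
  expect_equal(error_ratio(tf, 2L), 1)
  expect_warning(e3 <- error_ratio(tf, 3L), "zero force")
  expect_true(is.na(e3))
  expect_error(error_ratio(tf, 9L), "not present")
  expect_equal(cluster_net_force(tf, 1L), c(fx = 0, fy = 0))
  expect_equal(cluster_net_force(tf, 2L), c(fx = 0, fy = 2))
})

test_that("rms differences behave algebraically", {
  tx <- matrix(stats::rnorm(20), 5, 4); ty <- matrix(stats::rnorm(20), 5, 4)
  lab <- matrix(1L, 5, 4)
  region <- cluster_mask(grid_small, lab)
  tf_a <- traction_field(grid_small, tx, ty, labels = lab)
  tf_b <- traction_field(grid_small, 2 * tx, 2 * ty, labels = lab)
  expect_equal(unname(rms_difference(tf_a, tf_a, region)), c(0, 0))
  d <- rms_difference(tf_a, tf_b, region)
  expect_equal(d[["rms_traction"]], sqrt(mean(tx^2 + ty^2)))
  other <- traction_field(surface_grid(5, 4, 1), tx, ty, labels = lab)
  expect_error(rms_difference(tf_a, other, region), "alignment")
})

test_that("field constructors validate their inputs", {
  ux <- matrix(0, 5, 4)
  expect_error(surface_displacement_field(grid_small, ux, matrix(0, 4, 4)),
               "matrix")
  bad <- ux; bad[2, 2] <- NA
  d <- surface_displacement_field(grid_small, bad, ux)
  expect_false(d$valid[2, 2])
  expect_true(d$valid[1, 1])
  expect_error(
    surface_displacement_field(grid_small, bad, ux,
                               valid = matrix(TRUE, 5, 4)),
    "non-finite")
  expect_error(cluster_mask(grid_small, matrix(-1L, 5, 4)), "non-negative")
  expect_error(cluster_mask(grid_small, matrix(0.5, 5, 4)), "integer")
  fz_lab <- matrix(0L, 5, 4)
  fx <- matrix(0, 5, 4); fx[3, 3] <- 1
  expect_error(prescribed_force_field(grid_small, fx, matrix(0, 5, 4),
                                      labels = fz_lab), "unlabelled")
})

test_that("mask enlargement and bounding boxes behave as set operations", {
  lab <- matrix(0L, 7, 7)
  lab[4, 4] <- 1L
  m <- cluster_mask(surface_grid(7, 7, 1), lab)
  m1 <- enlarge_mask(m, 1L)
  expect_equal(sum(m1$labels > 0L), 5)          # von Neumann neighbourhood
  expect_true(all(m1$labels[m$labels > 0L] > 0L))
  m2 <- enlarge_mask(m, 2L)
  expect_equal(sum(m2$labels > 0L), 13)
  bb <- bounding_box_mask(m1, pad = 1L)
  expect_equal(sum(bb$labels > 0L), 25)
  expect_true(all(bb$labels[m1$labels > 0L] > 0L))
})

test_that("grid helpers report coordinates and identity", {
  expect_equal(grid_x(grid_small), c(-4, -2, 0, 2, 4))
  expect_equal(grid_y(grid_small), c(0, 3, 6, 9))
  mesh <- hex_mesh(4, 3, 5, c(1, 2, 0.5), origin = c(1, 1))
  expect_equal(mesh_n_nodes(mesh), 60)
  expect_equal(node_index(mesh, 1, 1, 1), 1)
  expect_equal(node_index(mesh, 4, 3, 5), 60)
  expect_equal(node_dof(10, 3), 30)
  sg <- mesh_surface_grid(mesh)
  expect_equal(sg$nx, 4)
  expect_equal(sg$spacing, c(1, 2))
  # fixed boundary = bottom plus walls; free surface = interior top nodes
  fb <- fixed_boundary_nodes(mesh)
  expect_equal(length(fb), 12 + 4 * (2 * 4 + 2 * 3 - 4))
  fs <- free_surface_nodes(mesh)
  expect_equal(length(fs), (4 - 2) * (3 - 2))
})
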