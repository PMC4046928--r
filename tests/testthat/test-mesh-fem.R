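test_that("hex element is symmetric, PSD, with exactly six rigid-body modes", {
  for (integ in c("selective", "full")) {
    K <- hex8_stiffness(1, 0.3, 1, 2, 3, integration = integ)
    expect_identical(K, t(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-10 * max(ev)), 6)
    expect_true(min(ev) > -1e-12 * max(ev))
    # unit rigid translations cost no energy
    for (a in 1:3) {
      u <- rep(0, 24); u[seq(a, 24, by = 3)] <- 1
      expect_lt(max(abs(K %*% u)), 1e-12 * max(abs(K)))
    }
  }
})

test_that("hex element reproduces the uniaxial closed form at nu = 0", {
  # E = 1 kPa unit cube under eps_x = 0.01: sigma_x = E * eps = 0.01 kPa,
  # face force 0.01 nN shared by 4 nodes -> +/- 0.0025 nN, no lateral force
  K <- hex8_stiffness(1, 0, 1, 1, 1)
  nat <- tractionfem:::hex8_natural_coords()
  xyz <- (nat + 1) / 2
  u <- rep(0, 24)
  u[seq(1, 24, by = 3)] <- 0.01 * xyz[, 1]
  f <- as.numeric(K %*% u)
  fx <- f[seq(1, 24, by = 3)]
  expect_equal(fx, ifelse(xyz[, 1] > 0.5, 0.0025, -0.0025), tolerance = 1e-12)
  expect_lt(max(abs(f[-seq(1, 24, by = 3)])), 1e-15)
})

test_that("invalid material or geometry is rejected", {
  expect_error(hex8_stiffness(1, 0.5, 1, 1, 1), "0.5")
  expect_error(hex8_stiffness(1, -0.1, 1, 1, 1))
  expect_error(hex8_stiffness(-1, 0.3, 1, 1, 1))
  expect_error(hex8_stiffness(1, 0.3, 0, 1, 1), "positive")
  expect_error(substrate_model(1, 0.5, 70), "0.5")
  expect_error(substrate_model(0, 0.3, 70))
  expect_error(substrate_model(1, 0.3, -5))
})

test_that("global assembly matches direct element scattering", {
  sub <- substrate_model(2, 0.25, 1)
  # a single element: global matrix IS the element matrix
  mesh1 <- hex_mesh(2, 2, 2, c(1, 1, 1))
  K1 <- as.matrix(assemble_global(mesh1, sub))
  Ke <- hex8_stiffness(2, 0.25, 1, 1, 1)
  expect_equal(K1, Ke, tolerance = 1e-14)
  # two elements along x: hand-scattered sum
  mesh2 <- hex_mesh(3, 2, 2, c(1, 1, 1))
  K2 <- as.matrix(assemble_global(mesh2, sub))
  Kref <- matrix(0, 36, 36)
  for (b in 1:2) {
    conn <- b + c(0, 1, 3, 4, 6, 7, 9, 10)
    ed <- as.vector(t(outer(3 * (conn - 1), 1:3, `+`)))
    Kref[ed, ed] <- Kref[ed, ed] + Ke
  }
  expect_equal(K2, Kref, tolerance = 1e-14)
  # equilibrium of the unloaded body: rigid translation in the null space
  for (a in 1:3) {
    t_mode <- rep(0, 36); t_mode[seq(a, 36, by = 3)] <- 1
    expect_lt(max(abs(K2 %*% t_mode)), 1e-12)
  }
})

test_that("assembly validates mesh/substrate consistency", {
  mesh <- hex_mesh(3, 3, 3, c(1, 1, 1))
  expect_error(assemble_global(mesh, substrate_model(1, 0.3, 5)), "thickness")
  expect_error(
    assemble_global(mesh, substrate_model(1, 0.3, 2, lateral_size_x = 9)),
    "lateral")
})

test_that("sparse mixed solve agrees with a dense brute-force partition solve", {
  mesh <- hex_mesh(3, 3, 3, c(1.2, 0.8, 1.1))
  sub <- substrate_model(1.5, 0.33, 2.2)
  K <- assemble_global(mesh, sub)
  n <- nrow(K)
  set.seed(101)
  d <- sort(sample(n, 30))
  dv <- stats::rnorm(30, sd = 0.1)
  fidx <- setdiff(seq_len(n), d)
  fv <- stats::rnorm(length(fidx), sd = 0.01)
  bc <- mixed_bc_set(n)
  bc <- prescribe_displacement(bc, d, dv)
  bc <- prescribe_force(bc, fidx, fv)
  sol <- solve_mbvp(K, bc)
  Kd <- as.matrix(K)
  u_oracle <- numeric(n)
  u_oracle[d] <- dv
  u_oracle[fidx] <- solve(Kd[fidx, fidx],
                          fv - Kd[fidx, d, drop = FALSE] %*% dv)
  expect_equal(sol$u, u_oracle, tolerance = 1e-10)
  # reactions at force DOFs are zero; global force balance per axis
  expect_true(all(sol$reactions[fidx] == 0))
  for (a in 1:3) {
    ax <- seq(a, n, by = 3)
    balance <- sum(sol$reactions[ax]) + sum(fv[fidx %in% ax])
    expect_lt(abs(balance), 1e-8 * (sum(abs(sol$reactions)) + sum(abs(fv))))
  }
})

test_that("mixed solve is linear and exact in degenerate cases", {
  mesh <- hex_mesh(3, 3, 3, c(1, 1, 1))
  sub <- substrate_model(1, 0.4, 2)
  K <- assemble_global(mesh, sub)
  n <- nrow(K)
  # all DOFs clamped to zero
  bc0 <- prescribe_displacement(mixed_bc_set(n), seq_len(n), 0)
  sol0 <- solve_mbvp(K, bc0)
  expect_true(all(sol0$u == 0))
  expect_true(all(sol0$reactions == 0))
  # scaling the BCs scales the whole solution
  set.seed(7)
  d <- sort(sample(n, 40)); dv <- stats::rnorm(40, sd = 0.05)
  bc1 <- prescribe_displacement(mixed_bc_set(n), d, dv)
  bc3 <- prescribe_displacement(mixed_bc_set(n), d, 3 * dv)
  s1 <- solve_mbvp(K, bc1); s3 <- solve_mbvp(K, bc3)
  expect_equal(s3$u, 3 * s1$u, tolerance = 1e-10)
  expect_equal(s3$reactions, 3 * s1$reactions, tolerance = 1e-10)
})

test_that("unconstrained rigid modes are reported as errors", {
  mesh <- hex_mesh(2, 2, 2, c(1, 1, 1))
  K <- assemble_global(mesh, substrate_model(1, 0.3, 1))
  expect_error(solve_mbvp(K, mixed_bc_set(24)), "rigid")
  # a single constrained DOF still leaves free rigid modes (CHOLMOD also
  # warns on the indefinite matrix before our error fires)
  bc <- prescribe_displacement(mixed_bc_set(24), 1L, 0)
  suppressWarnings(expect_error(solve_mbvp(K, bc), "positive definite|rigid"))
})

test_that("uniform-strain patch test is exact on a distorted-size mesh", {
  mesh <- hex_mesh(5, 4, 4, c(1.3, 0.9, 1.1))
  sub <- substrate_model(2, 0.47, 3.3)
  K <- assemble_global(mesh, sub)
  A <- matrix(c(0.01, 0.004, -0.002,
                0.004, -0.006, 0.003,
                -0.002, 0.003, 0.005), 3, 3)
  i <- rep(seq_len(mesh$nx), times = mesh$ny * mesh$nz)
  j <- rep(rep(seq_len(mesh$ny), each = mesh$nx), times = mesh$nz)
  k <- rep(seq_len(mesh$nz), each = mesh$nx * mesh$ny)
  X <- cbind((i - 1) * mesh$spacing[1], (j - 1) * mesh$spacing[2],
             (k - 1) * mesh$spacing[3])
  U <- X %*% t(A)
  on_boundary <- i %in% c(1, mesh$nx) | j %in% c(1, mesh$ny) | k %in% c(1, mesh$nz)
  bn <- which(on_boundary)
  bc <- prescribe_displacement(mixed_bc_set(3 * nrow(X)),
                               node_dof(rep(bn, each = 3), rep(1:3, length(bn))),
                               as.vector(t(U[bn, ])))
  sol <- solve_mbvp(K, bc)
  U_fem <- matrix(sol$u, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(U_fem - U)) / max(abs(U)), 1e-10)
})

test_that("factorization cache returns identical solutions", {
  mesh <- hex_mesh(3, 3, 3, c(1, 1, 1))
  K <- assemble_global(mesh, substrate_model(1, 0.3, 2))
  n <- nrow(K)
  d <- seq_len(27)  # first 9 nodes clamped
  bc <- prescribe_displacement(mixed_bc_set(n), d, 0)
  bc <- prescribe_force(bc, n, 0.5)
  cache <- new.env()
  s1 <- solve_mbvp(K, bc, cache = cache)
  s2 <- solve_mbvp(K, bc, cache = cache)
  expect_identical(s1$u, s2$u)
  expect_gt(length(ls(cache)), 0)
})
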