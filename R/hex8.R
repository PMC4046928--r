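#' Isotropic elasticity matrix (engineering strain ordering)
#'
#' Voigt ordering (exx, eyy, ezz, gxy, gyz, gzx).  Units: kPa.
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return 6 x 6 material stiffness matrix.
#' @export
elastic_d_matrix <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("E must be positive")
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5) {
    stop("Poisson's ratio must lie in [0, 0.5)")
  }
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Local node order of the trilinear hexahedron: lexicographic in the
# (i, j, k) offsets (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),
# (0,1,1),(1,1,1) -- the same order the global mesh numbering uses, so
# element connectivity is base-node + fixed offsets.
hex8_natural_coords <- function() {
  offs <- as.matrix(expand.grid(i = 0:1, j = 0:1, k = 0:1))
  2 * offs - 1  # rows: nodes; cols: (xi, eta, zeta) in {-1, +1}
}

#' Stiffness matrix of an 8-node trilinear hexahedral element
#'
#' Axis-aligned box element `hx x hy x hz`, three displacement DOFs per
#' node ordered (x, y, z), node-major.  This is the "small cube" building
#' block of the substrate model.  Selective reduced integration is used:
#' the deviatoric (shear) part of the material response is integrated with
#' the full 2 x 2 x 2 Gauss rule, the volumetric (lambda) part with a
#' single centre point.  Soft gels sit close to the incompressible limit
#' (nu = 0.45-0.48), where the fully integrated trilinear element locks
#' volumetrically and badly over-stiffens; one-point integration of the
#' volumetric term is the standard cure and leaves the element
#' patch-test exact.  Units: kPa x um = nN/um.
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @param hx,hy,hz Element edge lengths, um.
#' @param integration `"selective"` (default; volumetric term
#'   under-integrated, locking-free near nu = 0.5) or `"full"` (plain
#'   2 x 2 x 2 quadrature throughout; preferable for near-singular point
#'   load fields at moderate nu, where selective integration shows mild
#'   pressure-mode oscillations).
#' @return Symmetric positive semi-definite 24 x 24 matrix with exactly six
#'   zero-energy (rigid body) modes.
#' @export
hex8_stiffness <- function(E, nu, hx, hy, hz,
                           integration = c("selective", "full")) {
  integration <- match.arg(integration)
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0) {
    stop("E must be positive")
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu >= 0.5) {
    stop("Poisson's ratio must lie in [0, 0.5)")
  }
  if (any(!is.finite(c(hx, hy, hz))) || any(c(hx, hy, hz) <= 0)) {
    stop("element dimensions must be positive")
  }
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  # split D = D_mu + D_lambda: shear part (full quadrature) and volumetric
  # part lambda * m m' (one-point quadrature)
  D_mu <- diag(c(2 * mu, 2 * mu, 2 * mu, mu, mu, mu))
  m_vol <- c(1, 1, 1, 0, 0, 0)
  D_lam <- lambda * tcrossprod(m_vol)

  nat <- hex8_natural_coords()
  detJ <- hx * hy * hz / 8
  sc <- c(2 / hx, 2 / hy, 2 / hz)   # natural -> physical derivative scale
  b_at <- function(xi, eta, zeta) {
    dN <- cbind(
      nat[, 1] * (1 + nat[, 2] * eta) * (1 + nat[, 3] * zeta),
      (1 + nat[, 1] * xi) * nat[, 2] * (1 + nat[, 3] * zeta),
      (1 + nat[, 1] * xi) * (1 + nat[, 2] * eta) * nat[, 3]
    ) / 8
    dNx <- dN[, 1] * sc[1]; dNy <- dN[, 2] * sc[2]; dNz <- dN[, 3] * sc[3]
    B <- matrix(0, 6, 24)
    cx <- 3 * (0:7) + 1
    B[1, cx]     <- dNx
    B[2, cx + 1] <- dNy
    B[3, cx + 2] <- dNz
    B[4, cx]     <- dNy; B[4, cx + 1] <- dNx
    B[5, cx + 1] <- dNz; B[5, cx + 2] <- dNy
    B[6, cx]     <- dNz; B[6, cx + 2] <- dNx
    B
  }
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  K <- matrix(0, 24, 24)
  if (integration == "selective") {
    for (q in seq_len(nrow(gp))) {
      B <- b_at(gp[q, 1], gp[q, 2], gp[q, 3])
      K <- K + crossprod(B, D_mu %*% B) * detJ
    }
    B0 <- b_at(0, 0, 0)
    K <- K + crossprod(B0, D_lam %*% B0) * (8 * detJ)
  } else {
    D <- D_mu + D_lam
    for (q in seq_len(nrow(gp))) {
      B <- b_at(gp[q, 1], gp[q, 2], gp[q, 3])
      K <- K + crossprod(B, D %*% B) * detJ
    }
  }
  (K + t(K)) / 2
}

#' Assemble the global stiffness matrix of a uniform hexahedral mesh
#'
#' All elements share one element matrix (uniform spacing, homogeneous
#' material), so assembly reduces to scattering a single 24 x 24 block over
#' the structured connectivity.  Deterministic: node order is lexicographic
#' (`i` fastest), DOFs (x, y, z) per node.
#'
#' @param mesh A [hex_mesh()].
#' @param substrate A [substrate_model()]; its thickness must match the mesh
#'   height to 1e-6 relative.
#' @param integration Element quadrature, see [hex8_stiffness()].
#' @return Sparse symmetric (`dsCMatrix`) stiffness matrix over
#'   `3 * nx * ny * nz` DOFs, units nN/um.
#' @export
assemble_global <- function(mesh, substrate,
                            integration = c("selective", "full")) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(substrate, "substrate_model"))
  height <- (mesh$nz - 1L) * mesh$spacing[3]
  if (abs(height - substrate$thickness) > 1e-6 * max(1, substrate$thickness)) {
    stop("mesh height (", signif(height, 8), " um) does not span the substrate thickness (",
         substrate$thickness, " um)")
  }
  ext <- grid_extent(mesh_surface_grid(mesh))
  for (ax in 1:2) {
    ls <- c(substrate$lateral_size_x, substrate$lateral_size_y)[ax]
    if (!is.na(ls) && abs(ls - ext[ax]) > 1e-6 * max(1, ls)) {
      stop("mesh lateral extent does not match substrate lateral size on axis ",
           c("x", "y")[ax])
    }
  }
  Ke <- hex8_stiffness(substrate$youngs_modulus, substrate$poissons_ratio,
                       mesh$spacing[1], mesh$spacing[2], mesh$spacing[3],
                       integration = integration)
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  n_dof <- 3 * nx * ny * nz
  # base (lowest-index) node of every element, lexicographic
  base <- as.vector(outer(
    as.vector(outer(seq_len(nx - 1L), (seq_len(ny - 1L) - 1L) * nx, `+`)),
    (seq_len(nz - 1L) - 1L) * nx * ny, `+`
  ))
  offs <- c(0L, 1L, nx, nx + 1L, nx * ny, nx * ny + 1L, nx * ny + nx, nx * ny + nx + 1L)
  conn <- outer(base, offs, `+`)               # nelem x 8 node indices
  edof <- matrix(0, nrow(conn), 24)            # nelem x 24 DOF indices
  for (l in 1:8) for (a in 1:3) edof[, 3 * (l - 1) + a] <- 3 * (conn[, l] - 1) + a
  rsel <- rep(1:24, times = 24)
  csel <- rep(1:24, each = 24)
  keep <- rsel <= csel                 # scatter the upper triangle only
  rsel <- rsel[keep]; csel <- csel[keep]
  KeUp <- as.vector(Ke)[as.vector(upper.tri(Ke, diag = TRUE))]
  # scatter in element chunks to cap transient triplet memory on large meshes
  nelem <- nrow(edof)
  chunk <- max(1L, min(nelem, as.integer(2e7 / length(rsel))))
  starts <- seq(1L, nelem, by = chunk)
  K <- NULL
  for (s in starts) {
    sel <- s:min(s + chunk - 1L, nelem)
    ed <- edof[sel, , drop = FALSE]
    ii <- as.vector(ed[, rsel])
    jj <- as.vector(ed[, csel])
    swap <- ii > jj                    # keep (row <= col) in the global matrix
    tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
    Kc <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(KeUp, each = length(sel)),
                               dims = c(n_dof, n_dof))
    K <- if (is.null(K)) Kc else K + Kc
  }
  Matrix::forceSymmetric(K, uplo = "U")
}
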