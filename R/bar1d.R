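#' Stiffness matrix of a 1D elastic bar
#'
#' A chain of linear springs: `n` element stiffnesses connect `n + 1` nodes.
#' The assembled matrix is symmetric tridiagonal with zero row sums (a rigid
#' translation costs no energy).  This small model is the clearest place to
#' see why a mixed boundary value problem has a unique solution: prescribing
#' some displacements and the complementary forces always determines the
#' rest.
#'
#' @param k Positive element stiffnesses, nN/um.
#' @return Dense `(n+1) x (n+1)` stiffness matrix.
#' @export
#' @examples
#' bar_stiffness_1d(c(1, 1))
bar_stiffness_1d <- function(k) {
  if (length(k) < 1L || any(!is.finite(k)) || any(k <= 0)) {
    stop("element stiffnesses must be positive numbers")
  }
  n <- length(k)
  K <- matrix(0, n + 1, n + 1)
  for (e in seq_len(n)) {
    idx <- c(e, e + 1)
    K[idx, idx] <- K[idx, idx] + k[e] * matrix(c(1, -1, -1, 1), 2, 2)
  }
  K
}

#' Solve the 1D bar under mixed boundary conditions
#'
#' At every node either the displacement or the force is prescribed; the
#' solver returns the complementary unknowns.  With `k = c(1, 1)`,
#' `u1 = 0`, `u2 = -1`, `F3 = 0` the solution is `F1 = +1`, `F2 = -1`,
#' `u3 = -1`: a clamped node can carry force, and a force-free node can
#' move.  The nodal forces always sum to zero -- the load the "cell" puts on
#' the bar is self-equilibrated.
#'
#' @param k Element stiffnesses, nN/um (length `n`, for `n + 1` nodes).
#' @param displacements Numeric vector length `n + 1`; `NA` where the
#'   displacement is unknown (a force must be given there instead).
#' @param forces Numeric vector length `n + 1`; `NA` where the force is
#'   unknown.  Exactly one of displacement/force must be given per node.
#' @return A list with `u` and `F`, both length `n + 1`, fully determined.
#' @export
#' @examples
#' bar_solve_mbvp(c(1, 1), displacements = c(0, -1, NA), forces = c(NA, NA, 0))
bar_solve_mbvp <- function(k, displacements, forces) {
  K <- bar_stiffness_1d(k)
  n_nodes <- length(k) + 1L
  if (length(displacements) != n_nodes || length(forces) != n_nodes) {
    stop("`displacements` and `forces` must have one entry per node (", n_nodes, ")")
  }
  has_u <- !is.na(displacements)
  has_f <- !is.na(forces)
  if (any(has_u & has_f)) stop("a node may have either a displacement or a force, not both")
  if (any(!has_u & !has_f)) stop("every node needs a displacement or a force prescription")
  if (!any(has_u)) {
    stop("rank-deficient problem: with only forces prescribed the bar can ",
         "translate rigidly")
  }
  bc <- mixed_bc_set(n_nodes)
  bc <- prescribe_displacement(bc, which(has_u), displacements[has_u])
  bc <- prescribe_force(bc, which(has_f), forces[has_f])
  sol <- solve_mbvp(Matrix::Matrix(K, sparse = TRUE), bc)
  F_out <- forces
  F_out[has_u] <- sol$reactions[has_u]
  list(u = sol$u, F = F_out)
}
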