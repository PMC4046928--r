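#' Mixed boundary-condition set over the degrees of freedom of a model
#'
#' Every node-axis pair carries exactly one prescription: either a
#' displacement (um) or a force (nN).  The default prescription is zero
#' force, the natural (traction-free) condition, so only deviations need to
#' be set.
#'
#' @param n_dofs Total number of degrees of freedom.
#' @return An object of class `mixed_bc_set`.
#' @seealso [prescribe_displacement()], [prescribe_force()], [solve_mbvp()]
#' @export
mixed_bc_set <- function(n_dofs) {
  n_dofs <- as.integer(n_dofs)
  if (is.na(n_dofs) || n_dofs < 1L) stop("`n_dofs` must be a positive integer")
  structure(
    list(
      n_dofs = n_dofs,
      is_displacement = logical(n_dofs),
      value = numeric(n_dofs)
    ),
    class = "mixed_bc_set"
  )
}

#' Prescribe displacements at DOFs
#' @param bc A [mixed_bc_set()].
#' @param dofs DOF indices.
#' @param values Displacement values, um (recycled).
#' @return The updated `mixed_bc_set`.
#' @export
prescribe_displacement <- function(bc, dofs, values) {
  stopifnot(inherits(bc, "mixed_bc_set"))
  check_dofs(bc, dofs)
  if (any(!is.finite(values))) stop("prescribed displacements must be finite")
  bc$is_displacement[dofs] <- TRUE
  bc$value[dofs] <- values
  bc
}

#' Prescribe forces at DOFs
#' @param bc A [mixed_bc_set()].
#' @param dofs DOF indices.
#' @param values Force values, nN (recycled).
#' @return The updated `mixed_bc_set`.
#' @export
prescribe_force <- function(bc, dofs, values) {
  stopifnot(inherits(bc, "mixed_bc_set"))
  check_dofs(bc, dofs)
  if (any(!is.finite(values))) stop("prescribed forces must be finite")
  bc$is_displacement[dofs] <- FALSE
  bc$value[dofs] <- values
  bc
}

check_dofs <- function(bc, dofs) {
  if (length(dofs) == 0L) return(invisible())
  if (any(dofs < 1 | dofs > bc$n_dofs)) stop("DOF index out of range")
  if (anyDuplicated(dofs)) stop("duplicate DOF indices in one prescription")
  invisible()
}

#' Solver options
#'
#' @param tolerance Relative residual tolerance for the solve (checked for
#'   the direct path, iterated to for the conjugate-gradient path).
#' @param direct_max_dofs Problems whose total DOF count is at most this use
#'   a sparse Cholesky factorization; larger ones a Jacobi-preconditioned
#'   conjugate gradient.
#' @param cg_max_iter Iteration cap for the conjugate-gradient path.
#' @return A list of class `fem_solver_options`.
#' @export
fem_solver_options <- function(tolerance = 1e-8, direct_max_dofs = 1e5,
                               cg_max_iter = 20000L) {
  structure(
    list(tolerance = tolerance, direct_max_dofs = direct_max_dofs,
         cg_max_iter = as.integer(cg_max_iter)),
    class = "fem_solver_options"
  )
}

#' Solve a mixed boundary value problem
#'
#' Partitions the DOFs into the displacement-prescribed (Dirichlet) and
#' force-prescribed (Neumann) sets, solves the reduced linear system for the
#' unknown displacements, and recovers the reactions at the Dirichlet DOFs
#' as the residual `(K u - f)` there.  The reactions are therefore exactly
#' the external forces that must act at those DOFs for equilibrium -- for a
#' traction recovery they are the cell's nodal forces.
#'
#' @param K Global stiffness matrix (sparse symmetric), nN/um.
#' @param bc A [mixed_bc_set()] over the same DOFs.
#' @param options A [fem_solver_options()].
#' @param cache Optional environment.  When the same `K` is solved
#'   repeatedly under the same Dirichlet partition (as in the iterative
#'   whole-field scheme) the factorization is reused.
#' @return A list of class `fem_solution` with elements `u` (displacements
#'   at every DOF, um), `reactions` (forces at Dirichlet DOFs, nN; zero
#'   elsewhere), `dirichlet` (logical mask), and `residual` (relative
#'   residual of the reduced solve).
#' @export
solve_mbvp <- function(K, bc, options = fem_solver_options(), cache = NULL) {
  stopifnot(inherits(bc, "mixed_bc_set"))
  n <- nrow(K)
  if (n != bc$n_dofs) stop("BC set and stiffness matrix sizes differ")
  d <- which(bc$is_displacement)
  if (length(d) == 0L) {
    stop("rank-deficient problem: no displacements prescribed, all six ",
         "rigid-body modes are free")
  }
  f <- which(!bc$is_displacement)
  u <- numeric(n)
  u[d] <- bc$value[d]
  rhs_forces <- bc$value[f]

  if (length(f) > 0L) {
    sol <- mbvp_reduced_solve(K, d, f, u[d], rhs_forces, options, cache)
    u[f] <- sol$u_free
    residual <- sol$residual
  } else {
    residual <- 0
  }

  r_full <- as.numeric(K %*% u)
  reactions <- numeric(n)
  reactions[d] <- r_full[d]   # no external force is prescribed at Dirichlet DOFs
  structure(
    list(u = u, reactions = reactions,
         dirichlet = bc$is_displacement, residual = residual),
    class = "fem_solution"
  )
}

# Solve K[f,f] u_f = rhs - K[f,d] u_d, direct or CG depending on size.
mbvp_reduced_solve <- function(K, d, f, u_d, forces_f, options, cache = NULL) {
  key <- NULL
  entry <- NULL
  if (!is.null(cache)) {
    key <- rlang::hash(list(length(d), d))
    entry <- if (exists(key, envir = cache, inherits = FALSE)) get(key, envir = cache) else NULL
  }
  if (is.null(entry)) {
    Kff <- K[f, f, drop = FALSE]
    Kfd <- K[f, d, drop = FALSE]
    entry <- list(Kff = Kff, Kfd = Kfd, factor = NULL)
    if (nrow(K) <= options$direct_max_dofs) {
      entry$factor <- tryCatch(
        Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, super = TRUE),
        error = function(e) {
          stop("reduced stiffness matrix is not positive definite: a rigid-body ",
               "mode is unconstrained (", conditionMessage(e), ")")
        }
      )
    } else {
      # general storage gives much faster matrix-vector products in CG
      entry$Kff <- methods::as(Matrix::forceSymmetric(Kff), "generalMatrix")
    }
    if (!is.null(cache)) assign(key, entry, envir = cache)
  }
  rhs <- forces_f - as.numeric(entry$Kfd %*% u_d)
  rhs_scale <- sqrt(sum(rhs^2))
  if (rhs_scale == 0) {
    return(list(u_free = numeric(length(f)), residual = 0))
  }
  if (!is.null(entry$factor)) {
    u_f <- as.numeric(Matrix::solve(entry$factor, rhs, system = "A"))
  } else {
    u_f <- pcg_solve(entry$Kff, rhs, tol = options$tolerance,
                     max_iter = options$cg_max_iter)
  }
  residual <- sqrt(sum((as.numeric(entry$Kff %*% u_f) - rhs)^2)) / rhs_scale
  if (residual > max(options$tolerance, 1e-7)) {
    stop("solver residual ", signif(residual, 3), " exceeds tolerance ",
         options$tolerance)
  }
  list(u_free = u_f, residual = residual)
}

# Jacobi-preconditioned conjugate gradient for SPD sparse systems.
pcg_solve <- function(A, b, tol = 1e-8, max_iter = 20000L, x0 = NULL) {
  dinv <- 1 / Matrix::diag(A)
  if (any(!is.finite(dinv))) stop("zero diagonal in reduced system")
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - as.numeric(A %*% x)
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b_norm) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate gradient did not converge in ", max_iter,
       " iterations (relative residual ", signif(sqrt(sum(r^2)) / b_norm, 3), ")")
}
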