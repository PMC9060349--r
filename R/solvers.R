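#' Local response matrix by direct inversion
#'
#' Recovers the matrix of local interaction strengths `r` from a global
#' response matrix `R` with the closed form
#' \deqn{r = -[\mathrm{diag}(R^{-1})]^{-1} R^{-1},}
#' the consequence of the steady-state relation `rR = -P` (with `P` diagonal)
#' under the normalization `r[i, i] = -1`. `r[i, j]` is the direct, signed
#' influence of module `j` on module `i`, net of effects propagated through
#' the rest of the network: positive entries are activations, negative
#' entries inhibitions.
#'
#' The diagonal of the result is set to exactly -1 after solving: it is a
#' definition, not an estimate, so floating-point drift is overridden.
#'
#' @param R square global response matrix (see [global_response()]).
#' @param cond_cap refuse to solve when the 1-norm condition estimate of `R`
#'   exceeds this cap (default `1e12`); the error carries the estimate.
#' @param ridge optional Tikhonov term: solve with `R + ridge * I` instead
#'   of `R`. Off (0) by default and intended for exploratory use only; the
#'   estimator itself is unregularized.
#' @return `n x n` local response matrix with diagonal -1.
#' @seealso [solve_local_blockwise()] for the parallelizable formulation,
#'   [recover_sensitivities()] for the diagonal of `P`.
#' @export
solve_local_inverse <- function(R, cond_cap = 1e12, ridge = 0) {
  R <- check_square_named(R, "R")
  stopifnot(is.numeric(cond_cap), cond_cap > 0, is.numeric(ridge), ridge >= 0)
  Rw <- R
  if (ridge > 0) diag(Rw) <- diag(Rw) + ridge
  kappa1 <- condition_estimate(Rw)
  if (!is.finite(kappa1) || kappa1 > cond_cap)
    stop(sprintf(
      "global response matrix is singular or ill-conditioned (1-norm condition estimate %.3e exceeds cap %.3e)",
      kappa1, cond_cap))
  Rinv <- solve(Rw)
  d <- diag(Rinv)
  if (any(d == 0))
    stop("diag(R^-1) has zero entries; local responses are not identifiable")
  r <- -Rinv / d          # rows scaled by 1/diag(R^-1)
  diag(r) <- -1
  dimnames(r) <- dimnames(R)
  r
}

#' Local response matrix by independent blockwise LU solves
#'
#' Solves for the local response matrix row by row. For each module `i` the
#' homogeneous steady-state relations over the perturbations `k != i`,
#' \deqn{R_{i,k} = \sum_{j \ne i} r_{i,j} R_{j,k},}
#' form a linear system of dimension `n - 1` in the unknowns
#' `{r[i, j] : j != i}`. The `n` systems are mutually independent, so they
#' can be dispatched to parallel workers; each is solved by LU factorization
#' with partial pivoting (LAPACK `dgesv`). Results are assembled in fixed
#' row order, so the output is bit-identical for any worker count.
#'
#' @param R square global response matrix.
#' @param workers number of parallel processes (forked; 1 = serial). The
#'   result does not depend on this value.
#' @return the local response matrix (diagonal -1), with an attribute
#'   `"diagnostics"`: a list with `condition_estimate` (1-norm condition
#'   estimate of `R`), `pivot_warnings` (number of subsystems whose
#'   reciprocal condition fell below `1e-12`), and
#'   `per_subsystem_residuals` (max absolute residual of each solved
#'   system).
#' @export
solve_local_blockwise <- function(R, workers = 1L) {
  R <- check_square_named(R, "R")
  workers <- as.integer(workers)
  stopifnot(length(workers) == 1L, workers >= 1L)
  n <- nrow(R)
  if (n < 2L) stop("at least two modules are required")

  solve_row <- function(i) {
    A <- t(R[-i, -i, drop = FALSE])  # A[k, j] = R[j, k] over k, j != i
    b <- R[i, -i]
    x <- tryCatch(solve(A, b), error = function(e)
      stop(sprintf("subsystem for module %d ('%s') is singular: %s",
                   i, rownames(R)[i], conditionMessage(e)), call. = FALSE))
    list(x = x,
         residual = max(abs(A %*% x - b)),
         rcond = rcond(A))
  }

  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(n), solve_row, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n), solve_row)
  }
  # forked workers report errors as 'try-error' objects; surface them
  bad <- vapply(rows, inherits, logical(1L), what = c("try-error", "condition"))
  if (any(bad)) stop(attr(rows[[which(bad)[1L]]], "condition"))

  r <- matrix(0, n, n, dimnames = dimnames(R))
  for (i in seq_len(n)) r[i, -i] <- rows[[i]]$x   # fixed row order
  diag(r) <- -1
  rc <- vapply(rows, `[[`, numeric(1L), "rcond")
  attr(r, "diagnostics") <- list(
    condition_estimate = condition_estimate(R),
    pivot_warnings = sum(rc < 1e-12),
    per_subsystem_residuals = vapply(rows, `[[`, numeric(1L), "residual"))
  r
}

#' Recover the sensitivity diagonal
#'
#' Given the local response matrix `r` and the global response matrix `R`,
#' recovers the diagonal entries of the perturbation-sensitivity matrix `P`
#' from the inhomogeneous steady-state relation for the self-perturbation:
#' \deqn{P_{i,i} = R_{i,i} - \sum_{j \ne i} r_{i,j} R_{j,i}.}
#' `P[i, i]` is the product of the sensitivity of module `i` to its own
#' intrinsic parameter and the relative parameter change; only this product
#' is identifiable. The assembled diagonal satisfies `r %*% R == -P` up to
#' numerical tolerance.
#'
#' @param r local response matrix (diagonal -1).
#' @param R global response matrix of matching shape.
#' @return named numeric vector of the `P[i, i]`.
#' @export
recover_sensitivities <- function(r, R) {
  r <- check_square_named(r, "r")
  R <- check_square_named(R, "R")
  if (!identical(dim(r), dim(R)))
    stop("'r' and 'R' must have the same shape")
  # with r[i,i] = -1, -(rR)[i,i] = R[i,i] - sum_{j != i} r[i,j] R[j,i],
  # the only sign convention under which rR = -P holds
  P <- -rowSums(r * t(R))
  names(P) <- rownames(R)
  P
}

# reciprocal of LAPACK's 1-norm reciprocal condition estimate
condition_estimate <- function(M) {
  rc <- tryCatch(rcond(M, norm = "O"), error = function(e) 0)
  if (rc <= 0) Inf else 1 / rc
}
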