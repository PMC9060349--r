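#' Global response matrix from perturbation data
#'
#' Computes the matrix `R` of relative global responses, `R[i, k]` being the
#' relative steady-state change of module `i` when module `k` alone is
#' perturbed. On the positive-abundance scale the stable symmetric
#' relative-difference estimator is used,
#' \deqn{R_{i,k} = 2\,\frac{x_i^{(k)} - x_i^0}{x_i^{(k)} + x_i^0},}
#' which is bounded in \[-2, 2\]. On the signed z-score scale (consensus
#' signatures) the denominator is replaced by the sum of absolute values,
#' \deqn{R_{i,k} = 2\,\frac{x_i^{(k)} - x_i^0}{|x_i^{(k)}| + |x_i^0|},}
#' which avoids divisions by near-zero sums of values with opposed signs.
#' In both variants a 0/0 entry (no signal in either condition) is defined
#' as 0: an unobservable change is treated as no change.
#'
#' The symmetric estimator trades a small O(strength) bias for robustness
#' to low basal values. The plain relative difference
#' \eqn{(x_i^{(k)} - x_i^0)/x_i^0} (`estimator = "relative"`,
#' positive-abundance scale only) is the textbook definition of the global
#' response coefficient; it is exact for linear kinetics at any
#' perturbation strength but blows up when a basal value approaches zero.
#'
#' @param data a [perturbation_dataset()].
#' @param estimator `"stable"` (default, the bounded symmetric formula) or
#'   `"relative"` (plain relative difference).
#' @return numeric `n x n` matrix `R` with module identifiers on both axes.
#' @examples
#' d <- perturbation_dataset(c("a", "b"), basal = c(1, 1),
#'                           perturbed = matrix(c(3, 1, 1, 0), 2))
#' global_response(d)   # R[1,1] = 2*(3-1)/(3+1) = 1
#' @export
global_response <- function(data, estimator = c("stable", "relative")) {
  stopifnot(inherits(data, "perturbation_dataset"))
  estimator <- match.arg(estimator)
  x0 <- data$basal
  xp <- data$perturbed
  if (estimator == "relative") {
    if (data$value_scale != "positive_abundance")
      stop("the relative estimator is defined on the positive_abundance scale only")
    if (any(x0 == 0))
      stop("the relative estimator requires strictly positive basal values")
    R <- (xp - x0) / x0
    dimnames(R) <- list(data$module_ids, data$module_ids)
    return(R)
  }
  num <- 2 * (xp - x0)
  den <- if (data$value_scale == "positive_abundance") xp + x0 else abs(xp) + abs(x0)
  R <- num / den
  R[den == 0] <- 0    # both conditions silent: no observable change
  dimnames(R) <- list(data$module_ids, data$module_ids)
  R
}

#' Average replicate global response matrices
#'
#' Entrywise arithmetic mean of a list of response matrices sharing the same
#' module set, the replicate-handling convention for plate-structured
#' experiments: one `R` matrix is computed per plate (or replicate) and the
#' matrices are averaged, rather than averaging raw expression first.
#'
#' @param batch non-empty list of `n x n` response matrices with identical
#'   dimnames.
#' @return the mean response matrix.
#' @export
average_response <- function(batch) {
  if (!is.list(batch) || length(batch) == 0L)
    stop("'batch' must be a non-empty list of response matrices")
  ref <- check_square_named(batch[[1L]], "batch[[1]]")
  for (i in seq_along(batch)) {
    M <- check_square_named(batch[[i]], sprintf("batch[[%d]]", i))
    if (!identical(dimnames(M), dimnames(ref)))
      stop("all response matrices must share the same module identifiers")
    batch[[i]] <- M
  }
  Reduce(`+`, batch) / length(batch)
}
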