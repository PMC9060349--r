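#' Discretize an expression matrix for entropy estimation
#'
#' Bins each gene's expression values independently across samples, the
#' preprocessing step for plug-in (maximum-likelihood) entropy estimation.
#' `equal_frequency` assigns near-equal sample counts per bin using ranks
#' (ties share a rank and therefore a bin); `equal_width` cuts the gene's
#' observed range into equal intervals. A constant gene falls into a single
#' bin, which correctly yields zero entropy.
#'
#' @param expr numeric `n x m` matrix, genes as rows, samples as columns
#'   (`m >= 2`).
#' @param n_bins number of bins, `>= 2`; default `ceiling(sqrt(m))`, the
#'   usual heuristic for plug-in estimators.
#' @param method `"equal_frequency"` (default) or `"equal_width"`.
#' @return object of class `"binned_expression"`: integer matrix of bin
#'   labels in `1..n_bins` with the input dimnames, plus attributes
#'   `n_bins` and `method`.
#' @export
discretize_expression <- function(expr, n_bins = NULL,
                                  method = c("equal_frequency", "equal_width")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (!is.numeric(expr) || any(!is.finite(expr)))
    stop("'expr' must be a finite numeric matrix")
  m <- ncol(expr)
  if (m < 2L) stop("at least two samples are required")
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(m))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be at least 2")
  bin_one <- function(x) {
    if (method == "equal_frequency") {
      rk <- rank(x, ties.method = "average")
      pmin(pmax(ceiling(n_bins * rk / m), 1L), n_bins)
    } else {
      rg <- range(x)
      if (rg[1L] == rg[2L]) return(rep(1L, m))
      pmin(pmax(ceiling(n_bins * (x - rg[1L]) / (rg[2L] - rg[1L])), 1L), n_bins)
    }
  }
  labels <- t(apply(expr, 1L, bin_one))
  storage.mode(labels) <- "integer"
  dimnames(labels) <- dimnames(expr)
  structure(labels, class = c("binned_expression", "matrix"),
            n_bins = n_bins, method = method)
}

#' Pairwise mutual information matrix
#'
#' Computes the symmetric matrix of pairwise mutual information between all
#' genes of a discretized expression matrix, using plug-in
#' (maximum-likelihood) entropies with natural logarithms:
#' \deqn{MI_{i,j} = H(X_i) + H(X_j) - H(X_i, X_j), \qquad
#'       H(X) = -\sum_k p(x_k) \ln p(x_k),}
#' with probabilities estimated as empirical frequencies over the samples.
#' The diagonal holds the marginal entropies `H(X_i)` (the self-information
#' limit of MI), a convention downstream code must not interpret as an
#' interaction.
#'
#' @param binned a [discretize_expression()] result (or any integer label
#'   matrix, genes as rows).
#' @return symmetric non-negative `n x n` matrix in nats; each off-diagonal
#'   entry is bounded by `min(H(X_i), H(X_j))`.
#' @export
mi_matrix <- function(binned) {
  labels <- unclass(binned)
  if (!is.matrix(labels)) stop("'binned' must be a label matrix")
  storage.mode(labels) <- "integer"
  n <- nrow(labels)
  m <- ncol(labels)
  nb <- max(attr(binned, "n_bins") %||% max(labels), max(labels))
  H <- apply(labels, 1L, function(x) plugin_entropy(tabulate(x, nb), m))
  MI <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xi <- labels[i, ]
    for (j in seq_len(i - 1L)) {
      joint <- tabulate(xi + nb * (labels[j, ] - 1L), nb * nb)
      Hij <- plugin_entropy(joint, m)
      MI[i, j] <- MI[j, i] <- max(0, H[i] + H[j] - Hij)
    }
  }
  diag(MI) <- H
  ids <- rownames(labels) %||% paste0("G", seq_len(n))
  dimnames(MI) <- list(ids, ids)
  MI
}

plugin_entropy <- function(counts, total) {
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CLR scores from a mutual information matrix
#'
#' The context-likelihood-of-relatedness normalization of an MI matrix:
#' each MI value is converted to z-scores against the background of its row
#' and of its column, clamped at zero, and the pair score is the
#' root-sum-of-squares
#' \deqn{z_{i,j} = \sqrt{z_i^2 + z_j^2}, \quad
#'       z_i = \max\{0, (MI_{i,j} - \mathrm{mean}(MI_{i,\cdot})) /
#'       \mathrm{sd}(MI_{i,\cdot})\}.}
#' Row means and standard deviations exclude the diagonal (the marginal
#' entropies would otherwise dominate the background statistics). A
#' zero-variance background contributes `z = 0`.
#'
#' @param MI symmetric MI matrix from [mi_matrix()].
#' @return symmetric non-negative score matrix with zero diagonal.
#' @export
clr_mi <- function(MI) {
  MI <- check_square_named(MI, "MI")
  n <- nrow(MI)
  if (n < 2L) stop("at least two genes are required")
  off <- MI
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sd_ <- apply(off, 1L, stats::sd, na.rm = TRUE)
  z <- (MI - mu) / ifelse(sd_ > 0, sd_, Inf)
  z[is.na(z) | z < 0] <- 0
  S <- sqrt(z^2 + t(z)^2)       # z_i row-wise, z_j = t(z) column-wise
  diag(S) <- 0
  dimnames(S) <- dimnames(MI)
  S
}

#' MRNET scores by maximum-relevance minimum-redundancy selection
#'
#' For each target gene `i`, candidate regulators are ranked by greedy
#' forward selection: the first pick maximizes `MI[i, j]` (maximum
#' relevance); each further candidate is scored by its relevance minus its
#' mean redundancy with the genes already selected,
#' \deqn{s_j = MI_{i,j} - \frac{1}{|S|}\sum_{k \in S} MI_{j,k},}
#' and selection stops when the best score is not positive. A selected
#' gene's edge score is its selection-time score (floored at 0); the final
#' matrix is symmetrized by the maximum over the two target roles.
#'
#' @param MI symmetric MI matrix from [mi_matrix()].
#' @return symmetric non-negative score matrix with zero diagonal.
#' @export
mrnet_scores <- function(MI) {
  MI <- check_square_named(MI, "MI")
  n <- nrow(MI)
  if (n < 2L) stop("at least two genes are required")
  S <- matrix(0, n, n, dimnames = dimnames(MI))
  for (i in seq_len(n)) {
    candidates <- setdiff(seq_len(n), i)
    selected <- integer(0L)
    red_sum <- numeric(n)                 # running sum of MI[j, selected]
    repeat {
      rel <- MI[i, candidates]
      score <- if (length(selected) == 0L) rel
               else rel - red_sum[candidates] / length(selected)
      best <- which.max(score)
      if (score[best] <= 0) break
      j <- candidates[best]
      S[i, j] <- max(S[i, j], score[best])
      selected <- c(selected, j)
      candidates <- candidates[-best]
      if (length(candidates) == 0L) break
      red_sum <- red_sum + MI[, j]
    }
  }
  out <- pmax(S, t(S))
  diag(out) <- 0
  out
}

#' ARACNE pruning by the data processing inequality
#'
#' Starts from the MI matrix, zeroes entries below a common threshold
#' `tau`, then applies the data processing inequality: if genes `i` and `j`
#' interact only through gene `k`, then
#' `MI[i, j] <= min(MI[i, k], MI[k, j])`, so within every triplet of
#' nonzero MI values the strictly weakest edge is an indirect-interaction
#' candidate and is removed. All triplet decisions are taken on the
#' thresholded input matrix and applied at once, so the result does not
#' depend on any enumeration order (no cascading). With `eps = 0` an edge
#' is removed only when strictly weakest in some triplet — a three-way tie
#' removes nothing; with `eps > 0` the rule becomes
#' `MI[i, j] <= min(...) - eps`.
#'
#' @param MI symmetric MI matrix from [mi_matrix()].
#' @param tau non-negative initial threshold applied to all entries
#'   (default 0).
#' @param eps non-negative DPI tolerance (default 0).
#' @return symmetric score matrix; surviving entries keep their MI values,
#'   removed and sub-threshold entries are 0, diagonal is 0.
#' @export
aracne_prune <- function(MI, tau = 0, eps = 0) {
  MI <- check_square_named(MI, "MI")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("'tau' must be a single non-negative number")
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0)
    stop("'eps' must be a single non-negative number")
  n <- nrow(MI)
  M <- MI
  diag(M) <- 0
  M[M < tau] <- 0
  removed <- matrix(FALSE, n, n)
  for (k in seq_len(n)) {
    ik <- M[, k]                                  # MI[i, k]
    if (all(ik == 0)) next
    lim <- pmin(matrix(ik, n, n), matrix(ik, n, n, byrow = TRUE))  # min(M[i,k], M[k,j])
    cond <- if (eps == 0) M < lim else M <= lim - eps
    cond <- cond & M > 0 & outer(ik > 0, ik > 0)  # all three edges nonzero
    cond[k, ] <- FALSE
    cond[, k] <- FALSE
    removed <- removed | cond
  }
  M[removed] <- 0
  diag(M) <- 0
  M
}
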