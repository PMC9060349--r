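#' Signed CLR normalization of a local response matrix
#'
#' Brings the entries of an inferred local response matrix to a common,
#' background-corrected scale before thresholding, adapting the CLR
#' (context likelihood of relatedness) z-score scheme to signed
#' interaction strengths. For each entry:
#' \deqn{z^{row}_{i,j} = (r_{i,j} - \bar r_{i,\cdot}) / \sigma_i, \quad
#'       z^{col}_{i,j} = (r_{i,j} - \bar r_{\cdot,j}) / \sigma_j,}
#' with \eqn{\sigma_i, \sigma_j} the standard deviations of row `i` and
#' column `j` (full rows/columns, including the -1 diagonal, which is part
#' of the background; sample standard deviation). The combined magnitude is
#' \eqn{w_{i,j} = \sqrt{(z^{row})^2 + (z^{col})^2}} and the score keeps the
#' sign of the underlying interaction:
#' \eqn{Z_{i,j} = \mathrm{sign}(r_{i,j})\, w_{i,j}}.
#'
#' Unlike the MI flavour of CLR, the adapted scheme applies no
#' `max(0, z)` clamp by default: negative z-scores carry information about
#' entries below their row/column background. The clamped variant is
#' available behind `clamp = TRUE` for comparison.
#'
#' A row or column with zero variance contributes `z = 0` rather than an
#' infinity. The diagonal of `Z` is computed like any other entry but is
#' excluded from edge selection downstream (it encodes the fixed -1
#' normalization, not an inference).
#'
#' @param r square local response matrix (`n >= 2`).
#' @param clamp apply `max(0, z)` to the row and column z-scores before
#'   combining, as the MI-based CLR does (default `FALSE`).
#' @return matrix `Z` of signed scores, same shape and dimnames as `r`.
#' @export
clr_signed <- function(r, clamp = FALSE) {
  r <- check_square_named(r, "r")
  n <- nrow(r)
  if (n < 2L) stop("at least two modules are required")
  row_mu <- rowMeans(r)
  col_mu <- colMeans(r)
  row_sd <- apply(r, 1L, stats::sd)
  col_sd <- apply(r, 2L, stats::sd)
  zr <- (r - row_mu) / ifelse(row_sd > 0, row_sd, Inf)       # sd = 0 -> z = 0
  zc <- sweep(r, 2L, col_mu) / rep(ifelse(col_sd > 0, col_sd, Inf),
                                   each = n)
  if (clamp) {
    zr <- pmax(zr, 0)
    zc <- pmax(zc, 0)
  }
  Z <- sign(r) * sqrt(zr^2 + zc^2)
  dimnames(Z) <- dimnames(r)
  Z
}

#' Threshold a score matrix on absolute value
#'
#' Sets entries with `|value| < tau` to zero, then reduces the matrix to an
#' undirected edge set (see [symmetrize_scores()]). Pairs whose score is 0
#' after thresholding are dropped.
#'
#' @param M square score matrix.
#' @param tau non-negative absolute threshold; `tau = 0` retains every
#'   nonzero off-diagonal entry.
#' @return an edge set (see [symmetrize_scores()]).
#' @export
threshold_absolute <- function(M, tau) {
  M <- check_square_named(M, "M")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("'tau' must be a single non-negative number")
  M[abs(M) < tau] <- 0
  symmetrize_scores(M, drop_zero = TRUE)
}

#' Reduce a directed score matrix to undirected scored pairs
#'
#' Evaluation against undirected references (interaction databases,
#' simulator topologies folded to pairs) loses direction and sign, so a
#' directed score matrix is folded onto the upper triangle: each unordered
#' pair `{i, j}` receives the score `max(|M[i, j]|, |M[j, i]|)`. The
#' diagonal is discarded.
#'
#' @param M square score matrix.
#' @param drop_zero drop pairs with score 0 (default `FALSE`: all
#'   `n(n-1)/2` pairs are returned).
#' @return a `data.frame` of class `"edge_set"` with columns `a`, `b`
#'   (module identifiers, `a` before `b` in matrix order), `score`
#'   (non-negative), and `sign` (sign of the dominant direction's entry in
#'   `M`; 0 for zero scores). Attributes: `modules` (identifier vector) and
#'   `n_pairs` (size of the pair universe, `n(n-1)/2`).
#' @export
symmetrize_scores <- function(M, drop_zero = FALSE) {
  M <- check_square_named(M, "M")
  n <- nrow(M)
  ids <- rownames(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)     # i < j, column-major order
  up <- M[ut]                                   # M[i, j]
  lo <- t(M)[ut]                                # M[j, i]
  dominant <- ifelse(abs(up) >= abs(lo), up, lo)
  edges <- data.frame(a = ids[ut[, 1L]], b = ids[ut[, 2L]],
                      score = pmax(abs(up), abs(lo)),
                      sign = sign(dominant),
                      stringsAsFactors = FALSE)
  if (drop_zero) edges <- edges[edges$score > 0, , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("edge_set", "data.frame"),
            modules = ids, n_pairs = n * (n - 1L) / 2L)
}

#' Select the top-scoring fraction of pairs
#'
#' Retains the `ceiling(fraction * U)` highest-scoring unordered pairs,
#' where `U = n(n-1)/2` is the full pair universe of the module set — the
#' uniform selection protocol that makes MRA-style and MI-based inferences
#' comparable. Ties are broken deterministically: score descending, then
#' identifier pair in lexicographic order. Pairs with score 0 are never
#' selected; if fewer nonzero-score pairs exist than requested, all of them
#' are returned and the shortfall is flagged (attribute `"shortfall"`,
#' also the number of missing pairs), mirroring sparse algorithms such as
#' ARACNE that may not return enough interactions.
#'
#' @param edges an edge set from [symmetrize_scores()] or
#'   [threshold_absolute()].
#' @param fraction fraction of the pair universe to retain, in `(0, 1]`.
#' @return an edge set of the selected pairs, ordered by the tie-broken
#'   ranking, with attributes `requested` (the target count) and
#'   `shortfall` (0 when the request was met).
#' @export
select_top_fraction <- function(edges, fraction) {
  stopifnot(inherits(edges, "edge_set"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  universe <- attr(edges, "n_pairs")
  k <- ceiling(fraction * universe)
  nz <- edges[edges$score > 0, , drop = FALSE]
  ord <- order(-nz$score, nz$a, nz$b, method = "radix")
  sel <- nz[utils::head(ord, k), , drop = FALSE]
  rownames(sel) <- NULL
  structure(sel, class = c("edge_set", "data.frame"),
            modules = attr(edges, "modules"), n_pairs = universe,
            requested = k, shortfall = max(0L, k - nrow(sel)))
}
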