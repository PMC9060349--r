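#' Reference interaction network over a module set
#'
#' Wraps an undirected reference edge list (a STRING-style resource or a
#' simulator ground truth) together with the module universe it is
#' evaluated against. Scores are confidences in `[0, 1]`; a 0-1000 integer
#' scale (the STRING combined-score dialect) is auto-detected and rescaled.
#' Edges touching modules outside the universe are dropped; self-pairs and
#' duplicate pairs are rejected.
#'
#' @param edges data.frame with columns `a`, `b` (module identifiers) and
#'   optionally `score` (defaults to 1).
#' @param modules character vector: the module universe (all
#'   `n(n-1)/2` unordered pairs form the evaluation universe).
#' @return data.frame of class `"reference_network"` with columns `a`, `b`
#'   (`a` before `b` in `modules` order), `score`; attributes `modules`
#'   and `n_pairs`.
#' @export
reference_network <- function(edges, modules) {
  stopifnot(is.data.frame(edges), all(c("a", "b") %in% names(edges)))
  modules <- as.character(modules)
  if (anyDuplicated(modules)) stop("module universe must be unique")
  a <- as.character(edges$a)
  b <- as.character(edges$b)
  score <- if ("score" %in% names(edges)) as.numeric(edges$score) else rep(1, nrow(edges))
  if (any(!is.finite(score)) || any(score < 0))
    stop("reference scores must be finite and non-negative")
  if (length(score) && max(score) > 1) {
    if (max(score) > 1000) stop("reference scores exceed the 0-1000 scale")
    message("reference scores look 0-1000 scaled; rescaling to [0, 1]")
    score <- score / 1000
  }
  keep <- a %in% modules & b %in% modules
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  if (any(a == b)) stop("self-pairs are not allowed in a reference network")
  ia <- match(a, modules); ib <- match(b, modules)
  swap <- ia > ib
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b)
  if (anyDuplicated(key)) {        # keep the best-supported record per pair
    ord <- order(key, -score)
    dup <- duplicated(key[ord])
    keep2 <- ord[!dup]
    a <- a[keep2]; b <- b[keep2]; score <- score[keep2]
  }
  out <- data.frame(a = a, b = b, score = score, stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  n <- length(modules)
  structure(out, class = c("reference_network", "data.frame"),
            modules = modules, n_pairs = n * (n - 1L) / 2L)
}

#' Filter a reference network by confidence score
#'
#' Keeps edges with confidence strictly greater than `min_score`,
#' supporting the usual evaluation regimes (all scored interactions
#' `> 0`, the default `> 0.5`, and the stringent `> 0.8`).
#'
#' @param ref a [reference_network()].
#' @param min_score threshold in `[0, 1)`.
#' @return the filtered reference network (same universe).
#' @export
filter_reference <- function(ref, min_score = 0.5) {
  stopifnot(inherits(ref, "reference_network"),
            min_score >= 0, min_score < 1)
  out <- ref[ref$score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(ref), modules = attr(ref, "modules"),
            n_pairs = attr(ref, "n_pairs"))
}

#' Confusion table of a selected edge set against a reference
#'
#' Intersects an undirected selected edge set with a reference network over
#' the same module universe and tabulates TP, FP, FN, TN over all
#' `n(n-1)/2` unordered pairs, together with specificity, accuracy,
#' precision, recall, and the hypergeometric enrichment p-value of the
#' overlap (see [hypergeom_overlap_test()]).
#'
#' @param selected an edge set (see [select_top_fraction()]).
#' @param ref a [reference_network()] over the same modules.
#' @return one-row data.frame: `TP`, `FP`, `FN`, `TN`, `specificity`,
#'   `accuracy`, `precision`, `recall`, `pvalue`.
#' @export
confusion_table <- function(selected, ref) {
  stopifnot(inherits(selected, "edge_set"), inherits(ref, "reference_network"))
  if (!setequal(attr(selected, "modules"), attr(ref, "modules")))
    stop("selected edges and reference are defined over different module sets")
  universe <- attr(ref, "n_pairs")
  sel_key <- pair_keys(selected$a, selected$b, attr(ref, "modules"))
  ref_key <- pair_keys(ref$a, ref$b, attr(ref, "modules"))
  TP <- length(intersect(sel_key, ref_key))
  FP <- length(sel_key) - TP
  FN <- length(ref_key) - TP
  TN <- universe - TP - FP - FN
  data.frame(
    TP = TP, FP = FP, FN = FN, TN = TN,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    accuracy = (TP + TN) / universe,
    precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
    recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    pvalue = hypergeom_overlap_test(TP, length(sel_key), length(ref_key),
                                    universe))
}

# canonical unordered-pair keys in module order
pair_keys <- function(a, b, modules) {
  ia <- match(a, modules); ib <- match(b, modules)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  paste(lo, hi)
}

#' Hypergeometric test for edge-set overlap
#'
#' Upper-tail probability `P(X >= overlap)` for
#' `X ~ Hypergeometric(universe, ref_size, selected)`: the chance that a
#' uniformly random selection of `selected` pairs from the universe hits at
#' least `overlap` reference pairs. This is the enrichment convention
#' (tail includes the observed overlap); `overlap = 0` gives `p = 1`.
#'
#' @param overlap observed number of shared pairs.
#' @param selected number of selected pairs.
#' @param ref_size number of reference pairs.
#' @param universe total number of candidate pairs, `n(n-1)/2`.
#' @return the upper-tail probability.
#' @export
hypergeom_overlap_test <- function(overlap, selected, ref_size, universe) {
  stopifnot(overlap >= 0, selected >= 0, ref_size >= 0, universe >= 0,
            selected <= universe, ref_size <= universe,
            overlap <= min(selected, ref_size))
  stats::phyper(overlap - 1, ref_size, universe - ref_size, selected,
                lower.tail = FALSE)
}

#' Run the full algorithm-comparison protocol
#'
#' Applies MRA, MRA+CLR, and the MI baselines CLR, MRNET and ARACNE to one
#' perturbation dataset, selects the top-scoring fraction of pairs at each
#' requested level with the identical protocol for every algorithm, and
#' scores each selection against the reference network. Algorithms whose
#' score matrix holds fewer nonzero pairs than a selection level requests
#' are flagged (`shortfall`) and their metrics set to `NA` at that level,
#' so sparse outputs are ignored rather than padded.
#'
#' MRA scores are `|r|` from the blockwise solver; MRA+CLR scores are the
#' signed CLR normalization `|Z|` of the same `r`. The MI baselines run on
#' the condition matrix (basal + all perturbed profiles as samples) after
#' equal-frequency discretization.
#'
#' @param data a [perturbation_dataset()].
#' @param ref a [reference_network()] over the same modules.
#' @param fractions selection levels (default `c(0.05, 0.1, 0.2, 0.3, 0.4)`).
#' @param workers worker count for the blockwise solver.
#' @param n_bins,aracne_tau,aracne_eps tuning of the MI baselines (see
#'   [discretize_expression()] and [aracne_prune()]).
#' @return data.frame with one row per (algorithm, fraction): selection
#'   size, shortfall flag, and the [confusion_table()] columns.
#' @export
compare_algorithms <- function(data, ref,
                               fractions = c(0.05, 0.1, 0.2, 0.3, 0.4),
                               workers = 1L, n_bins = NULL,
                               aracne_tau = 0, aracne_eps = 0) {
  stopifnot(inherits(data, "perturbation_dataset"),
            inherits(ref, "reference_network"))
  R <- global_response(data)
  r <- solve_local_blockwise(R, workers = workers)
  Z <- clr_signed(r)
  expr <- condition_matrix(data)
  MI <- mi_matrix(discretize_expression(expr, n_bins = n_bins))
  scores <- list(
    MRA = r * (1 - diag(1, nrow(r))),     # drop the -1 diagonal from selection
    `MRA+CLR` = Z * (1 - diag(1, nrow(Z))),
    CLR = clr_mi(MI),
    MRNET = mrnet_scores(MI),
    ARACNE = aracne_prune(MI, tau = aracne_tau, eps = aracne_eps))
  out <- list()
  for (alg in names(scores)) {
    edges <- symmetrize_scores(scores[[alg]])
    for (f in fractions) {
      sel <- select_top_fraction(edges, f)
      short <- attr(sel, "shortfall") > 0L
      ct <- if (short) {
        data.frame(TP = NA_integer_, FP = NA_integer_, FN = NA_integer_,
                   TN = NA_integer_, specificity = NA_real_,
                   accuracy = NA_real_, precision = NA_real_,
                   recall = NA_real_, pvalue = NA_real_)
      } else {
        confusion_table(sel, ref)
      }
      out[[length(out) + 1L]] <- cbind(
        data.frame(algorithm = alg, fraction = f, selected = nrow(sel),
                   shortfall = short, stringsAsFactors = FALSE), ct)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
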