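# Independent brute-force oracles used to freeze or cross-check expected
# values. These deliberately use plain loops and direct formula
# transcriptions, not the package's vectorized code paths.

# entrywise signed CLR recomputation with explicit two-pass mean/sd
oracle_clr_signed <- function(r) {
  n <- nrow(r)
  Z <- matrix(0, n, n, dimnames = dimnames(r))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    row <- r[i, ]; col <- r[, j]
    sr <- stats::sd(row); sc <- stats::sd(col)
    zr <- if (sr > 0) (r[i, j] - mean(row)) / sr else 0
    zc <- if (sc > 0) (r[i, j] - mean(col)) / sc else 0
    Z[i, j] <- sign(r[i, j]) * sqrt(zr^2 + zc^2)
  }
  Z
}

# plug-in MI from the empirical joint table of two label vectors
oracle_mi <- function(x, y) {
  m <- length(x)
  joint <- table(x, y) / m
  px <- rowSums(joint); py <- colSums(joint)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H(px) + H(py) - H(as.numeric(joint))
}

# DPI pruning by exhaustive enumeration of all unordered triplets
oracle_aracne <- function(MI, tau = 0, eps = 0) {
  n <- nrow(MI)
  M <- MI; diag(M) <- 0
  M[M < tau] <- 0
  drop <- matrix(FALSE, n, n)
  if (n >= 3L) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      e <- c(M[i, j], M[i, k], M[j, k])
      if (any(e == 0)) next
      weakest <- which(if (eps == 0) e < pmin(e[c(2, 1, 1)], e[c(3, 3, 2)])
                       else e <= pmin(e[c(2, 1, 1)], e[c(3, 3, 2)]) - eps)
      pairs <- rbind(c(i, j), c(i, k), c(j, k))
      for (w in weakest) {
        drop[pairs[w, 1], pairs[w, 2]] <- TRUE
        drop[pairs[w, 2], pairs[w, 1]] <- TRUE
      }
    }
  }
  M[drop] <- 0
  M
}

# plain transcription of MRMR forward selection per target, max-symmetrized
oracle_mrnet <- function(MI) {
  n <- nrow(MI)
  S <- matrix(0, n, n, dimnames = dimnames(MI))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    sel <- integer(0)
    while (length(cand) > 0) {
      sc <- vapply(cand, function(j) {
        red <- if (length(sel)) mean(MI[j, sel]) else 0
        MI[i, j] - red
      }, numeric(1))
      b <- which.max(sc)
      if (sc[b] <= 0) break
      S[i, cand[b]] <- max(S[i, cand[b]], sc[b])
      sel <- c(sel, cand[b])
      cand <- cand[-b]
    }
  }
  pmax(S, t(S))
}

# closed-form hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(overlap, selected, ref_size, universe) {
  ks <- overlap:min(selected, ref_size)
  sum(choose(ref_size, ks) * choose(universe - ref_size, selected - ks)) /
    choose(universe, selected)
}

# well-conditioned random response matrix via the forward construction
random_response <- function(n, seed, sparsity = 0.2) {
  linear_mra_instance(n, sparsity = sparsity, seed = seed)$R
}

# undirected ground-truth reference of a simulated network
truth_reference <- function(net) {
  reference_network(
    data.frame(a = net$edges$regulator, b = net$edges$target),
    net$module_ids)
}
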