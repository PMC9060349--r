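test_that("discretization defaults and rules behave as documented", {
  expr <- matrix(rnorm(27), 3, 9)
  b <- discretize_expression(expr)
  expect_equal(attr(b, "n_bins"), 3L)              # ceiling(sqrt(9))
  expect_true(all(b >= 1L & b <= 3L))
  # equal width on 1..10 with 2 bins splits at the midpoint
  ew <- discretize_expression(rbind(1:10, 1:10), n_bins = 2, method = "equal_width")
  expect_equal(unname(ew[1, ]), rep(1:2, each = 5))
  # constant gene: one occupied bin, zero entropy
  cst <- discretize_expression(rbind(rep(2, 6), rnorm(6)))
  expect_equal(length(unique(cst[1, ])), 1L)
  expect_equal(mi_matrix(cst)[1, 1], 0)
  expect_error(discretize_expression(matrix(1, 2, 1)), "two samples")
})

test_that("plug-in MI matches hand and joint-table oracles", {
  # joint counts [[2,0],[0,2]] over 4 samples: MI = ln 2
  lab <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2))
  rownames(lab) <- c("x", "y")
  MI <- mi_matrix(structure(lab, n_bins = 2L))
  expect_equal(MI["x", "y"], log(2))
  expect_equal(MI["x", "x"], log(2))               # diagonal holds H(X)
  # deterministic relabeling: MI equals the marginal entropy
  lab2 <- rbind(a = c(1, 2, 3, 1, 2, 3), b = c(3, 1, 2, 3, 1, 2))
  MI2 <- mi_matrix(structure(lab2, n_bins = 3L))
  expect_equal(MI2["a", "b"], MI2["a", "a"])
  # random toys vs the exhaustive joint-frequency oracle
  set.seed(1)
  for (rep in 1:5) {
    lab3 <- matrix(sample(1:3, 5 * 8, replace = TRUE), 5, 8)
    MI3 <- mi_matrix(structure(lab3, n_bins = 3L))
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(MI3[i, j], oracle_mi(lab3[i, ], lab3[j, ]))
    expect_equal(MI3, t(MI3))
    expect_true(all(MI3 >= -1e-12))
  }
})

test_that("MI is bounded by marginal entropies and unchanged by extra genes", {
  set.seed(2)
  lab <- matrix(sample(1:4, 6 * 20, replace = TRUE), 6, 20)
  MI <- mi_matrix(structure(lab, n_bins = 4L))
  H <- diag(MI)
  for (i in 1:5) for (j in (i + 1):6)
    expect_lte(MI[i, j], min(H[i], H[j]) + 1e-12)
  # appending an independent noise gene leaves existing pairwise MI intact
  lab2 <- rbind(lab, sample(1:4, 20, replace = TRUE))
  MI2 <- mi_matrix(structure(lab2, n_bins = 4L))
  expect_equal(unname(MI2[1:6, 1:6]), unname(MI))
})

test_that("MI-based CLR scores match an independent recomputation", {
  set.seed(4)
  MI <- matrix(runif(16, 0, 1), 4); MI <- (MI + t(MI)) / 2
  diag(MI) <- 2
  dimnames(MI) <- list(paste0("g", 1:4), paste0("g", 1:4))
  S <- clr_mi(MI)
  # two-pass oracle with diagonal excluded from the background
  for (i in 1:4) for (j in 1:4) {
    if (i == j) { expect_equal(S[i, j], 0); next }
    zi <- max(0, (MI[i, j] - mean(MI[i, -i])) / sd(MI[i, -i]))
    zj <- max(0, (MI[i, j] - mean(MI[-j, j])) / sd(MI[-j, j]))
    expect_equal(S[i, j], sqrt(zi^2 + zj^2))
  }
  # flat background: every score is zero
  flat <- matrix(0.4, 4, 4); diag(flat) <- 1
  dimnames(flat) <- dimnames(MI)
  expect_equal(unname(clr_mi(flat)), matrix(0, 4, 4))
  # one outstanding pair gets the strictly largest score
  up <- flat; up[1, 2] <- up[2, 1] <- 0.9
  Su <- clr_mi(up)
  expect_true(Su[1, 2] > max(Su[upper.tri(Su)][-1]))
})

test_that("MRNET equals the brute-force greedy trace", {
  # fully redundant third gene is dropped
  MI <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  MI[1, 2] <- MI[2, 1] <- 0.8
  MI[1, 3] <- MI[3, 1] <- 0.5
  MI[2, 3] <- MI[3, 2] <- 0.9
  diag(MI) <- 1
  S <- mrnet_scores(MI)
  expect_equal(S[1, 3], 0)                    # redundant given gene 2
  expect_equal(S[1, 2], 0.8)
  expect_equal(S[2, 3], 0.9)
  expect_equal(S, oracle_mrnet(MI))
  # two genes: the single edge is scored by its MI
  M2 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("a","b"), c("a","b")))
  expect_equal(mrnet_scores(M2)["a", "b"], 0.3)
  # star topology: hub-leaf edges carry the top scores
  hub <- matrix(0.3, 5, 5); hub[1, ] <- hub[, 1] <- 0.8; diag(hub) <- 1.5
  dimnames(hub) <- list(paste0("g", 1:5), paste0("g", 1:5))
  Sh <- mrnet_scores(hub)
  expect_equal(Sh, oracle_mrnet(hub))
  expect_true(min(Sh[1, -1]) >= max(Sh[-1, -1][upper.tri(Sh[-1, -1])]))
  # random instances vs oracle
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 2
    dimnames(M) <- list(paste0("g", 1:n), paste0("g", 1:n))
    expect_equal(mrnet_scores(M), oracle_mrnet(M))
  }
})

test_that("ARACNE pruning equals the exhaustive triplet oracle", {
  # printed weakest-of-triplet rule
  MI <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  MI[1, 2] <- MI[2, 1] <- 0.2
  MI[1, 3] <- MI[3, 1] <- 0.5
  MI[2, 3] <- MI[3, 2] <- 0.4
  out <- aracne_prune(MI)
  expect_equal(out[1, 2], 0)                  # weakest edge removed
  expect_equal(out[1, 3], 0.5)
  expect_equal(out[2, 3], 0.4)
  # exact three-way tie: nothing is strictly weakest, nothing removed
  tie <- matrix(0.3, 3, 3); diag(tie) <- 0
  dimnames(tie) <- dimnames(MI)
  expect_equal(aracne_prune(tie), tie)
  # eps tightens removal: an edge must be weaker by at least eps
  near <- MI; near[1, 2] <- near[2, 1] <- 0.38
  expect_equal(aracne_prune(near, eps = 0.05)[1, 2], 0.38)  # within eps: kept
  expect_equal(aracne_prune(near, eps = 0.01)[1, 2], 0)     # beyond eps: removed
  # random 5-6 gene matrices vs brute force, with and without tau/eps
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(5:6, 1)
    M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tau <- sample(c(0, 0.2), 1); eps <- sample(c(0, 0.05), 1)
    got <- aracne_prune(M, tau = tau, eps = eps)
    expect_equal(got, oracle_aracne(M, tau = tau, eps = eps))
    # pruning only removes: surviving edges keep their MI values
    expect_true(all(got[got > 0] == M[got > 0]))
    expect_true(all((got > 0) <= (M >= tau)))
  }
})
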