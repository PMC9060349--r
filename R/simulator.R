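#' Generate a random TF/TA regulatory network with kinetics
#'
#' Samples a ground-truth gene regulatory network in the two-class style of
#' steady-state network generators: `n_tf` regulator genes (TFs — genes
#' able to control the expression of other genes, possibly looping back
#' into the network) and `n_ta` pure target genes (TAs) with no outgoing
#' edges. Every gene draws its regulators among the TFs only; self-edges
#' are excluded. Edge signs are activating with probability
#' `activation_fraction`, inhibiting otherwise, with weight magnitudes
#' uniform in `[0.5, 1.5]` before stabilization.
#'
#' Kinetics are sampled alongside the topology: per-gene degradation rates
#' `d` uniform in `[0.5, 1.5]`, target basal steady states uniform in
#' `[1, 3]`, and synthesis rates `b` derived so that the unperturbed linear
#' system `dx/dt = b + W x - D x` has exactly those steady states. The
#' weight matrix is then shrunk geometrically (factor 0.8) until (i) the
#' linear operator `W - D` has spectral abscissa at most -0.05, so a stable
#' steady state exists, and (ii) all synthesis rates are positive, so the
#' basal expression of every gene is a genuine positive abundance.
#'
#' @param n_tf number of regulator genes (`>= 2`).
#' @param n_ta number of pure target genes (`>= 0`).
#' @param mean_degree mean in-degree (regulators per gene); must not exceed
#'   the number of available TF parents.
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @param activation_fraction probability that an edge activates
#'   (default 0.7, the activator-rich regime typical of transcriptional
#'   networks).
#' @return object of class `"ground_truth_network"`: list with
#'   `module_ids`, `n_tf`, `n_ta`, `W` (signed weighted adjacency,
#'   regulator `j` -> target `i` in `W[i, j]`), `synthesis`, `degradation`,
#'   `seed`, and `edges` (data.frame: regulator, target, sign, weight).
#' @export
generate_topology <- function(n_tf, n_ta, mean_degree = 2, seed = 1L,
                              activation_fraction = 0.7) {
  stopifnot(n_tf >= 2L, n_ta >= 0L, mean_degree >= 0)
  n <- n_tf + n_ta
  if (mean_degree > n_tf - 1L)
    stop("'mean_degree' exceeds the number of available TF parents")
  ids <- c(sprintf("TF%03d", seq_len(n_tf)),
           if (n_ta > 0L) sprintf("TA%04d", seq_len(n_ta)))
  rng <- local_rng(seed)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    parents <- setdiff(seq_len(n_tf), i)     # TFs only, no self-edge
    k <- min(length(parents), stats::rpois(1L, mean_degree))
    if (k == 0L) next
    pa <- sample(parents, k)
    w <- stats::runif(k, 0.5, 1.5) *
      ifelse(stats::runif(k) < activation_fraction, 1, -1)
    W[i, pa] <- w
  }
  d <- stats::runif(n, 0.5, 1.5)
  x_target <- stats::runif(n, 1, 3)
  restore_rng(rng)

  # stabilize; synthesis must stay positive for the chosen basal states
  for (iter in seq_len(200L)) {
    b <- (diag(d, n) - W) %*% x_target
    ok <- max(Re(eigen(W - diag(d, n), only.values = TRUE)$values)) <= -0.05 &&
      all(b > 0)
    if (ok) break
    W <- 0.8 * W
  }
  if (!ok) stop("could not stabilize the sampled network")
  b <- as.numeric(b)
  names(b) <- names(d) <- ids

  idx <- which(W != 0, arr.ind = TRUE)
  edges <- data.frame(regulator = ids[idx[, 2L]], target = ids[idx[, 1L]],
                      sign = sign(W[idx]), weight = abs(W[idx]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(module_ids = ids, n_tf = as.integer(n_tf),
                 n_ta = as.integer(n_ta), W = W, synthesis = b,
                 degradation = d, seed = as.integer(seed), edges = edges),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("Ground-truth regulatory network: %d TFs, %d TAs, %d edges (seed %d)\n",
              x$n_tf, x$n_ta, nrow(x$edges), x$seed))
  invisible(x)
}

#' Simulation configuration
#'
#' @param mode `"linear"` (closed-form steady states of
#'   `dx/dt = b + W x - D x`) or `"hill"` (saturating Hill-type regulation,
#'   integrated to convergence).
#' @param perturbation_strength fraction of the perturbed gene's synthesis
#'   removed, in `(0, 1]`: 1 emulates a full knockout (CRISPR-like), small
#'   values a mild knockdown (shRNA-like). Defaults to 1.
#' @param noise_sd standard deviation (log scale) of multiplicative
#'   log-normal observation noise on all readouts; 0 = noise-free.
#' @param seed integer seed for the observation noise.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(mode = c("linear", "hill"), perturbation_strength = 1,
                       noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(perturbation_strength > 0, perturbation_strength <= 1,
            noise_sd >= 0)
  structure(list(mode = mode,
                 perturbation_strength = perturbation_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Steady state of a ground-truth network
#'
#' In linear mode returns the exact fixed point `x = (D - W)^{-1} b` of
#' `dx/dt = b + W x - D x`, after checking that the spectral abscissa of
#' `W - D` is negative (stability). In hill mode each gene's synthesis is
#' modulated by saturating Hill terms of its regulators
#' (activators `0.1 + 0.9 x^h / (K^h + x^h)`, inhibitors
#' `K^h / (K^h + x^h)`, `h = 2`, `K` at half the regulator's maximal
#' expression) and the ODE system is integrated from the basal condition
#' until the residual `max |dx/dt| < 1e-10`.
#'
#' @param net a [generate_topology()] network.
#' @param config a [sim_config()].
#' @param synthesis optional replacement synthesis vector (used internally
#'   to apply perturbations).
#' @return named steady-state activity vector (all entries non-negative).
#' @export
steady_state <- function(net, config = sim_config(), synthesis = NULL) {
  stopifnot(inherits(net, "ground_truth_network"), inherits(config, "sim_config"))
  b <- if (is.null(synthesis)) net$synthesis else synthesis
  n <- length(b)
  if (config$mode == "linear") {
    A <- net$W - diag(net$degradation, n)
    if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
      stop("linear system is unstable: no steady state")
    x <- solve(-A, b)
    names(x) <- net$module_ids
    return(x)
  }
  hill_steady(net, b)
}

# Hill-mode fixed point by integration to convergence
hill_steady <- function(net, b, tol = 1e-10, window = 50, max_windows = 400L) {
  n <- length(b)
  act <- net$W > 0
  inh <- net$W < 0
  K <- 0.5 * net$synthesis / net$degradation   # half of unregulated max
  h <- 2
  deriv <- function(t, x, parms) {
    xh <- x^h
    frac <- xh / (K^h + xh)                     # activation occupancy
    g <- exp(act %*% log(0.1 + 0.9 * frac) + inh %*% log(1 - frac))
    list(as.numeric(b * g - net$degradation * x))
  }
  x <- net$synthesis / net$degradation          # basal initial condition
  for (w in seq_len(max_windows)) {
    sol <- deSolve::ode(y = x, times = c(0, window), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    x <- pmax(sol[nrow(sol), -1L], 0)
    if (max(abs(deriv(0, x, NULL)[[1L]])) < tol) {
      names(x) <- net$module_ids
      return(x)
    }
  }
  stop("hill-mode integration did not converge to a steady state")
}

#' Simulate a full single-perturbation experiment
#'
#' Computes the basal steady state and, for each gene `k`, the steady state
#' with gene `k`'s synthesis rate scaled by
#' `1 - perturbation_strength` — the in-silico analogue of a systematic
#' knockdown (small strength) or knockout (strength 1) screen. Optional
#' multiplicative log-normal noise (mean 1) is applied to every readout.
#'
#' Readouts are floored at zero: abundances cannot be negative, and the
#' linear kinetics can transiently predict small negative values for a
#' strongly perturbed gene under net inhibition. The floor only bites at
#' large perturbation strengths, one of the mechanisms by which full
#' knockouts leave the linear-response regime where MRA is exact.
#'
#' @param net a [generate_topology()] network.
#' @param config a [sim_config()].
#' @return a [perturbation_dataset()] on the positive-abundance scale; the
#'   ground-truth network is attached as attribute `"truth"`.
#' @export
simulate_perturbations <- function(net, config = sim_config()) {
  stopifnot(inherits(net, "ground_truth_network"), inherits(config, "sim_config"))
  n <- length(net$module_ids)
  basal <- steady_state(net, config)
  perturbed <- matrix(0, n, n)
  for (k in seq_len(n)) {
    bk <- net$synthesis
    bk[k] <- bk[k] * (1 - config$perturbation_strength)
    perturbed[, k] <- steady_state(net, config, synthesis = bk)
  }
  if (config$noise_sd > 0) {
    rng <- local_rng(config$seed)
    sdl <- config$noise_sd
    basal <- basal * stats::rlnorm(n, -sdl^2 / 2, sdl)
    perturbed <- perturbed * matrix(stats::rlnorm(n * n, -sdl^2 / 2, sdl), n, n)
    restore_rng(rng)
  }
  perturbed <- pmax(perturbed, 0)   # abundance floor (see Details)
  out <- perturbation_dataset(net$module_ids, basal, perturbed,
                              value_scale = "positive_abundance")
  attr(out, "truth") <- net
  out
}

#' Ground-truth local response matrix of a linear network
#'
#' The local response coefficients implied by the linear kinetics at the
#' basal steady state: `r[i, j] = W[i, j] * x_j / (d_i * x_i)` for
#' `i != j` and `-1` on the diagonal (normalization of each row by the
#' gene's own degradation response). This is the target MRA should recover
#' in the small-perturbation limit.
#'
#' @param net a [generate_topology()] network (linear kinetics).
#' @return `n x n` matrix with diagonal -1.
#' @export
true_local_response <- function(net) {
  stopifnot(inherits(net, "ground_truth_network"))
  x <- steady_state(net, sim_config(mode = "linear"))
  r <- net$W * rep(x, each = length(x)) / (net$degradation * x)
  diag(r) <- -1
  dimnames(r) <- list(net$module_ids, net$module_ids)
  r
}

#' Exactly solvable forward-constructed MRA instance
#'
#' Builds a random sparse local response matrix `r_true` (diagonal -1,
#' off-diagonal entries present with probability `sparsity`, scaled so the
#' matrix is safely invertible), a random sensitivity diagonal `P_true`
#' with `|P[i, i]| >= 0.1`, and the corresponding global response matrix
#' \deqn{R = -r_{true}^{-1} P_{true},} so `r_true R = -P_true` holds
#' exactly. Such instances are exact-recovery oracles: any correct MRA
#' solver applied to `R` must return `r_true` and `P_true` up to numerical
#' round-off.
#'
#' @param n number of modules (`>= 2`).
#' @param sparsity probability that an off-diagonal entry of `r_true` is
#'   nonzero (default 0.2); 0 gives the decoupled instance `r = -I`,
#'   `R = P`.
#' @param seed integer seed.
#' @return list with elements `r_true`, `P_true` (named vector), `R`.
#' @export
linear_mra_instance <- function(n, sparsity = 0.2, seed = 1L) {
  stopifnot(n >= 2L, sparsity >= 0, sparsity <= 1)
  ids <- sprintf("M%04d", seq_len(n))
  rng <- local_rng(seed)
  for (attempt in seq_len(50L)) {
    r <- matrix(0, n, n)
    off <- which(row(r) != col(r))
    nz <- off[stats::runif(length(off)) < sparsity]
    r[nz] <- stats::runif(length(nz), 0.2, 1) * sample(c(-1, 1), length(nz), TRUE)
    diag(r) <- -1
    # shrink off-diagonal part until r = -(I - B) with spectral radius(B) < 0.9
    B <- r + diag(1, n)
    rho <- max(Mod(eigen(B, only.values = TRUE)$values))
    if (rho >= 0.9) r <- diag(-1, n) + (0.85 / rho) * B
    P <- stats::runif(n, 0.2, 1.5) * sample(c(-1, 1), n, TRUE)
    R <- tryCatch(-solve(r, diag(P, n)), error = function(e) NULL)
    if (!is.null(R) && all(is.finite(R)) && condition_estimate(R) < 1e8) break
    R <- NULL
  }
  restore_rng(rng)
  if (is.null(R)) stop("could not construct an invertible instance")
  dimnames(r) <- dimnames(R) <- list(ids, ids)
  names(P) <- ids
  list(r_true = r, P_true = P, R = R)
}

# seed the global RNG reproducibly, restoring the caller's state on exit
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
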