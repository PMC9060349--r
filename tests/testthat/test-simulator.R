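test_that("topology generation is seeded, TF/TA structured and bounded", {
  n1 <- generate_topology(10, 15, 2, seed = 4)
  n2 <- generate_topology(10, 15, 2, seed = 4)
  expect_identical(n1, n2)
  n3 <- generate_topology(10, 15, 2, seed = 5)
  expect_false(identical(n1$W, n3$W))
  # all edges are sourced from TFs; TAs have zero out-degree
  expect_true(all(n1$edges$regulator %in% n1$module_ids[1:10]))
  expect_true(all(n1$W[, 11:25] == 0))
  expect_true(all(diag(n1$W) == 0))
  expect_true(all(n1$degradation > 0))
  expect_true(all(n1$synthesis > 0))
  # pure TF network with feedback is a valid boundary case
  tf_only <- generate_topology(6, 0, 2, seed = 1)
  expect_length(tf_only$module_ids, 6L)
  expect_error(generate_topology(5, 5, mean_degree = 10), "mean_degree")
})

test_that("linear steady states match closed forms and are stable", {
  # no edges: x = b / d
  net <- generate_topology(4, 0, 0, seed = 2)
  net$W[] <- 0
  x <- steady_state(net, sim_config("linear"))
  expect_equal(unname(x), unname(net$synthesis / net$degradation))
  # single activating chain 1 -> 2: x2 = (b2 + w x1) / d2
  net$W[2, 1] <- 0.4
  x <- steady_state(net, sim_config("linear"))
  expect_equal(x[2], (net$synthesis[2] + 0.4 * x[1]) / net$degradation[2],
               ignore_attr = TRUE)
  # exact fixed point of the sampled system, residual at solver precision
  net2 <- generate_topology(12, 8, 2, seed = 6)
  x2 <- steady_state(net2, sim_config("linear"))
  resid <- net2$synthesis + net2$W %*% x2 - net2$degradation * x2
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("hill-mode integration converges to a tight steady state", {
  net <- generate_topology(10, 10, 2, seed = 13)
  x <- steady_state(net, sim_config("hill"))
  expect_true(all(x >= 0))
  # residual of the hill ODE at the returned point
  act <- net$W > 0; inh <- net$W < 0
  K <- 0.5 * net$synthesis / net$degradation
  frac <- x^2 / (K^2 + x^2)
  g <- exp(act %*% log(0.1 + 0.9 * frac) + inh %*% log(1 - frac))
  expect_lt(max(abs(net$synthesis * g - net$degradation * x)), 1e-9)
})

test_that("perturbation datasets are seeded, complete and KO-consistent", {
  net <- generate_topology(8, 4, 2, seed = 3)
  cfg <- sim_config("linear", perturbation_strength = 1)
  d1 <- simulate_perturbations(net, cfg)
  d2 <- simulate_perturbations(net, cfg)
  expect_identical(d1, d2)
  expect_s3_class(d1, "perturbation_dataset")
  expect_true(all(d1$perturbed >= 0))
  # a full KO of a gene whose only source is basal synthesis zeroes it
  orphan <- which(rowSums(net$W != 0) == 0)[1]
  expect_equal(unname(d1$perturbed[orphan, orphan]), 0)
  # noise changes readouts but is reproducible under the same seed
  nz <- sim_config("linear", perturbation_strength = 1, noise_sd = 0.1, seed = 9)
  dn1 <- simulate_perturbations(net, nz)
  dn2 <- simulate_perturbations(net, nz)
  expect_identical(dn1, dn2)
  expect_false(identical(dn1$perturbed, d1$perturbed))
})

test_that("small perturbations let MRA recover the network, large ones degrade it", {
  net <- generate_topology(10, 10, 2, seed = 17)
  rtrue <- true_local_response(net)
  err <- sapply(c(0.01, 0.2, 1.0), function(s) {
    d <- simulate_perturbations(net, sim_config("linear", perturbation_strength = s))
    max(abs(solve_local_blockwise(global_response(d)) - rtrue))
  })
  expect_true(all(diff(err) > 0))       # monotone degradation with strength
  # sign pattern of W is recovered exactly at small strength
  d <- simulate_perturbations(net, sim_config("linear", perturbation_strength = 0.01))
  rhat <- solve_local_blockwise(global_response(d))
  strong <- abs(rtrue) > 0.05 & row(rtrue) != col(rtrue)
  expect_equal(sign(rhat[strong]), sign(rtrue[strong]))
  # the plain relative estimator is exact even at full-KO strength when
  # no readout is floored
  d2 <- simulate_perturbations(net, sim_config("linear", perturbation_strength = 0.5))
  if (all(d2$perturbed > 0)) {
    r2 <- solve_local_blockwise(global_response(d2, estimator = "relative"))
    expect_lt(max(abs(r2 - rtrue)), 1e-8)
  }
})

test_that("forward-constructed instances are exact oracles by design", {
  # decoupled: sparsity 0 gives r = -I and R = P
  inst0 <- linear_mra_instance(5, sparsity = 0, seed = 1)
  expect_equal(unname(inst0$r_true), -diag(5))
  expect_equal(unname(inst0$R), unname(diag(inst0$P_true, 5)))
  # seeded determinism and the defining identity rR = -P
  i1 <- linear_mra_instance(20, 0.3, seed = 8)
  i2 <- linear_mra_instance(20, 0.3, seed = 8)
  expect_identical(i1, i2)
  expect_lt(max(abs(i1$r_true %*% i1$R + diag(i1$P_true, 20))), 1e-10)
  expect_true(all(abs(i1$P_true) >= 0.1))
  expect_identical(unname(diag(i1$r_true)), rep(-1, 20))
  # 2x2 instance obeys the closed-form relations
  i3 <- linear_mra_instance(2, 0.8, seed = 3)
  r <- solve_local_inverse(i3$R)
  expect_equal(r[1, 2], i3$R[1, 2] / i3$R[2, 2], ignore_attr = TRUE)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_topology(5, 5, 2, seed = 99))
  invisible(linear_mra_instance(5, seed = 99))
  b <- runif(1)
  expect_identical(a, b)
})
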