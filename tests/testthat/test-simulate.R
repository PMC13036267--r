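test_that("drawn curves have the designed component variances", {
  cfg <- sim_config(n = 10000, censor_rate = 0.1, seed = 13)
  set.seed(13)
  fd <- draw_functional(10000, cfg)
  xi <- attr(fd, "scores")
  lam1 <- true_eigenvalue(1)
  expect_equal(lam1, 0.4052847, tolerance = 1e-6)
  # Var estimate of a chi-square mean: MC se = lam1 * sqrt(2 / n)
  expect_lt(abs(var(xi[, 1]) - lam1), 3 * lam1 * sqrt(2 / 10000))
  # zero-mean process, pointwise
  expect_lt(max(abs(colMeans(fd$values))), 4 * sqrt(0.5 / 10000))
})

test_that("quadrature of the functional term equals the score contraction", {
  cfg <- sim_config(n = 50, censor_rate = 0.1, seed = 14)
  set.seed(14)
  fd <- draw_functional(50, cfg)
  xi <- attr(fd, "scores")
  b0 <- true_beta(fd$grid)
  lhs <- sapply(seq_len(50), function(i) oracle_trapz(fd$grid, fd$values[i, ] * b0))
  rhs <- drop(xi[, 1:2] %*% c(1, 3))
  # true eigenfunctions are only quadrature-orthonormal up to O(h^2)
  expect_equal(lhs, rhs, tolerance = 1e-3)
})

test_that("the exact score identity holds for estimated components", {
  # beta expanded in the *estimated* eigenfunctions: the quadrature integral
  # contracts exactly to the score sum
  cfg <- sim_config(n = 100, censor_rate = 0.1, seed = 15)
  set.seed(15)
  fd <- draw_functional(100, cfg)
  fp <- fpca(fd)
  eta <- c(1, 3, -0.5)
  beta <- drop(fp$eigenfunctions[, 1:3] %*% eta)
  w <- fvcox:::trapezoid_weights(fd$grid)
  lhs <- drop(fd$values %*% (w * beta))
  rhs <- drop(fp$scores[, 1:3] %*% eta)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("the true linear predictor evaluates the printed coefficients", {
  cfg <- sim_config(n = 10, censor_rate = 0.1, seed = 1)
  n <- 10
  V <- matrix(0, n, 3)
  Z <- matrix(0, n, 2)
  xi <- matrix(0, n, 2)
  expect_equal(linear_predictor(V, Z, runif(n), xi, cfg), rep(0, n))
  # U = 0: alpha1 = 2, alpha2 = -2 + 27/5 = 3.4
  Z1 <- cbind(rep(1, n), rep(1, n))
  expect_equal(linear_predictor(V, Z1, rep(0, n), xi, cfg), rep(2 + 3.4, n))
  # theta contribution
  V1 <- matrix(rep(c(1, 1, 1), each = n), n, 3)
  expect_equal(linear_predictor(V1, Z, rep(0, n), xi, cfg), rep(1.5, n))
  # alternative parse of the second varying coefficient
  cfg2 <- sim_config(n = 10, censor_rate = 0.1, alpha2_form = "power_3_5")
  expect_equal(
    linear_predictor(V, Z1, rep(0, n), xi, cfg2),
    rep(2 + (-2 + 3^0.6), n)
  )
})

test_that("survival times invert the cumulative hazard", {
  set.seed(16)
  t0 <- draw_survival_times(rep(0, 10000))
  ks <- suppressWarnings(ks.test(t0, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
  set.seed(17)
  t2 <- draw_survival_times(rep(log(2), 40000))
  expect_equal(mean(t2), 0.5, tolerance = 0.02)
  # proportional hazards: scaling the rate divides times accordingly
  set.seed(18)
  a <- draw_survival_times(rep(0, 40000))
  set.seed(18)
  b <- draw_survival_times(rep(1, 40000))
  expect_equal(a / b, rep(exp(1), 40000), tolerance = 1e-12)
})

test_that("censoring calibration hits the target rate", {
  # closed-form calibration against a large Monte Carlo oracle at lp = 0
  cc <- calibrate_censoring(rep(0, 100), 0.5)
  set.seed(19)
  Tt <- rexp(1e6)
  Cc <- runif(1e6, 0, cc)
  expect_equal(mean(Cc < Tt), 0.5, tolerance = 0.003)
  expect_error(calibrate_censoring(rep(0, 10), 1.2), "target_rate")

  # realized censoring on full simulations within binomial tolerance
  for (s in 1:3) {
    sim <- simulate_dataset(sim_config(n = 2000, censor_rate = 0.3, seed = 400 + s))
    expect_lt(abs(mean(sim$data$event == 0) - 0.3), 0.03)
  }
  # near-zero target: the bound grows and censoring vanishes
  c_small <- calibrate_censoring(rep(0, 100), 0.01)
  expect_gt(c_small, calibrate_censoring(rep(0, 100), 0.5))
})

test_that("simulated datasets are reproducible and well-formed", {
  s1 <- simulate_dataset(sim_config(n = 80, censor_rate = 0.3, seed = 5))
  s2 <- simulate_dataset(sim_config(n = 80, censor_rate = 0.3, seed = 5))
  expect_identical(s1$data, s2$data)
  expect_identical(s1$functional$values, s2$functional$values)
  expect_identical(s1$truth$scores, s2$truth$scores)
  s3 <- simulate_dataset(sim_config(n = 80, censor_rate = 0.3, seed = 6))
  expect_false(identical(s1$data$time, s3$data$time))
})

test_that("omitting covariates biases the fixed-coefficient estimate", {
  sim <- simulate_dataset(sim_config(n = 4000, censor_rate = 0.1, seed = 23))
  sd <- fvcox:::as_survival_dataset(sim$data)
  full_lp_rest <- true_alpha1(sim$data$U) * sim$data$Z1 +
    true_alpha2(sim$data$U) * sim$data$Z2 +
    drop(sim$truth$scores[, 1:2] %*% c(1, 3))
  # V-only working model: heavy omitted heterogeneity attenuates theta1
  red <- fit_cox(sd$V, sd$time, sd$event)
  oracle <- fit_cox(cbind(sd$V, full_lp_rest), sd$time, sd$event)
  expect_lt(red$coefficients[1], 0.8) # attenuated well below 1
  expect_lt(
    abs(oracle$coefficients[1] - 1),
    abs(red$coefficients[1] - 1)
  )
})

test_that("generated data satisfy proportional hazards at desk level", {
  # crude Schoenfeld-style check: residual of the event covariate against
  # its risk-set mean should be uncorrelated with event-time rank
  sim <- simulate_dataset(sim_config(n = 1500, censor_rate = 0.1, seed = 29))
  sd <- fvcox:::as_survival_dataset(sim$data)
  lp <- sim$truth$lp # correctly specified linear predictor
  ev_idx <- which(sd$event == 1)
  resid <- sapply(ev_idx, function(i) {
    risk <- which(sd$time >= sd$time[i])
    wgt <- exp(lp[risk])
    sd$V[i, 1] - sum(sd$V[risk, 1] * wgt) / sum(wgt)
  })
  ct <- cor.test(resid, rank(sd$time[ev_idx]))
  expect_gt(ct$p.value, 0.001)
})
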