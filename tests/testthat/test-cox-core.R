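tiny <- fvcox:::tiny_worked_fixture()

test_that("survival datasets validate their invariants", {
  expect_error(survival_dataset(c(1, -2), c(1, 0)), "positive")
  expect_error(survival_dataset(c(1, 2), c(0, 0)), "at least one")
  expect_error(survival_dataset(c(1, 2), c(1, 2)), "0/1")
  expect_error(
    survival_dataset(c(1, 2), c(1, 0), Z = cbind(c(1, 2))),
    "U is required"
  )
})

test_that("design expansion degenerates to a plain Cox design", {
  V <- cbind(a = c(1, 2, 3), b = c(0, 1, 0))
  sd <- survival_dataset(c(1, 2, 3), c(1, 1, 0), V = V)
  des <- build_design(sd)
  expect_equal(des$W, V, ignore_attr = TRUE)
  expect_identical(des$block_index$theta, 1:2)
  expect_length(des$block_index$eta, 0)
})

test_that("a constant varying coefficient collapses to one column", {
  # Z constant-basis expansion (kn = 0, order = 1): the varying coefficient
  # becomes a single scalar parameter
  sd <- survival_dataset(c(1, 2, 3), c(1, 1, 0),
    Z = cbind(c(2, -1, 0.5)), U = c(0.2, 0.5, 0.9)
  )
  spec <- spline_spec(0, 1, c(0, 1))
  des <- build_design(sd, spec)
  expect_equal(drop(des$W), c(2, -1, 0.5), ignore_attr = TRUE)

  # Z identically 1 gives an all-ones (intercept-like) column
  sd1 <- survival_dataset(c(1, 2, 3), c(1, 1, 0),
    Z = cbind(c(1, 1, 1)), U = c(0.2, 0.5, 0.9)
  )
  expect_equal(drop(build_design(sd1, spec)$W), rep(1, 3), ignore_attr = TRUE)
})

test_that("the worked 3-subject design matches hand computation", {
  fd <- tiny$functional
  sd <- fvcox:::as_survival_dataset(tiny$data, fd)
  fp <- fpca(fd)
  spec <- spline_spec(0, 2, c(0, 1)) # linear basis: B1 = 1-u, B2 = u
  des <- build_design(sd, spec, fp, m = 1)

  # quadrature norm of the leading curve shape on the 5-point grid,
  # written out independently: curves are c_i * sqrt(2) sin(pi t / 2)
  g <- c(0, 0.25, 0.5, 0.75, 1)
  phi <- sqrt(2) * sin(pi * g / 2)
  w <- c(0.125, 0.25, 0.25, 0.25, 0.125)
  s <- sqrt(sum(w * phi^2)) # FPCA normalizes the shape to quadrature norm 1
  cvec <- c(0.5, -1, 2)
  W_hand <- cbind(
    c(0.5, -0.2, 1.0), # V1
    c(1, 2, -1) * (1 - c(0, 0.5, 1)), # Z1 * B1(U)
    c(1, 2, -1) * c(0, 0.5, 1), # Z1 * B2(U)
    cvec * s # leading score
  )
  expect_equal(unname(des$W), W_hand, tolerance = 1e-12)
})

test_that("the null partial likelihood has its closed form", {
  sd <- fvcox:::as_survival_dataset(tiny$data)
  W <- matrix(rnorm(3), 3, 1)
  out <- neg_log_partial_likelihood(0, W, sd$time, sd$event)
  expect_equal(out$value, log(3) + log(2) + log(1), tolerance = 1e-14)
})

test_that("a two-subject likelihood matches hand enumeration", {
  # subjects with times (1, 2), both events, covariate w = (1, 0):
  # -Q(b) = -[b - log(e^b + 1)] - [0 - log(1)]
  for (b in c(-1, 0, 0.7, 3)) {
    out <- neg_log_partial_likelihood(b, cbind(c(1, 0)), c(1, 2), c(1, 1))
    expect_equal(out$value, -(b - log(exp(b) + 1)), tolerance = 1e-12)
  }
})

test_that("likelihood, gradient and Hessian match the brute-force oracle", {
  for (s in 1:20) {
    n <- sample(3:8, 1)
    d <- sample(1:3, 1)
    dat <- random_small_surv(n, d, seed = 300 + s)
    delta <- rnorm(d)
    out <- neg_log_partial_likelihood(delta, dat$W, dat$time, dat$event)
    f <- function(x) brute_neg_loglik(x, dat$W, dat$time, dat$event)
    expect_equal(out$value, f(delta), tolerance = 1e-12)
    expect_equal(out$gradient, fd_gradient(f, delta),
      tolerance = 1e-6, ignore_attr = TRUE
    )
    expect_equal(out$hessian, fd_hessian(f, delta),
      tolerance = 1e-4, ignore_attr = TRUE
    )
    # Hessian of the negative log partial likelihood is PSD
    expect_gte(min(eigen(out$hessian, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("the objective is convex along random segments", {
  dat <- random_small_surv(8, 2, seed = 77)
  set.seed(78)
  for (rep in 1:5) {
    d0 <- rnorm(2)
    d1 <- rnorm(2)
    ts <- seq(0, 1, length.out = 50)
    vals <- sapply(ts, function(t) {
      neg_log_partial_likelihood(
        (1 - t) * d0 + t * d1, dat$W, dat$time, dat$event,
        what = "value"
      )$value
    })
    expect_true(all(diff(vals, differences = 2) > -1e-8))
  }
})

test_that("tied event times use the Breslow denominator", {
  skip_if_not_installed("survival")
  set.seed(5)
  W <- matrix(rnorm(40), 20, 2)
  time <- rep(1:5, each = 4) # heavy ties
  event <- rbinom(20, 1, 0.8)
  event[1] <- 1
  fit <- fit_cox(W, time, event)
  cph <- survival::coxph(survival::Surv(time, event) ~ W, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(cph)), tolerance = 1e-6)
  expect_equal(fit$loglik, cph$loglik[2], tolerance = 1e-8)
})

test_that("Newton fits agree with an established Cox implementation", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 300
  W <- cbind(rnorm(n), rbinom(n, 1, 0.4))
  lp <- W %*% c(0.8, -0.5)
  time <- rexp(n, exp(lp))
  event <- rbinom(n, 1, 0.85)
  event[1] <- 1
  fit <- fit_cox(W, time, event)
  cph <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ W,
      ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, iter.max = 50)
    )
  )
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(cph)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cph)))), tolerance = 1e-6)
})

test_that("Newton coverage: estimates fall within 3 SE of the truth", {
  set.seed(31)
  hits <- replicate(40, {
    n <- 400
    W <- cbind(rnorm(n), rnorm(n))
    theta <- c(0.5, -0.3)
    time <- rexp(n, exp(W %*% theta))
    cens <- runif(n, 0, quantile(time, 0.95) * 2)
    ev <- as.integer(time <= cens)
    fit <- fit_cox(W, pmin(time, cens), pmax(ev, c(1, rep(0, n - 1))))
    all(abs(fit$coefficients - theta) < 3 * fit$se)
  })
  expect_gte(mean(hits), 0.90)
})

test_that("separation is flagged as monotone likelihood, not an error", {
  # two subjects, one covariate: the score is positive for every b, the
  # maximizer diverges
  fit <- fit_cox(cbind(c(1, 0)), c(1, 2), c(1, 1))
  expect_true(fit$monotone_likelihood)
  expect_false(fit$converged)
})

test_that("degenerate and rank-deficient inputs raise errors", {
  expect_error(fit_cox(cbind(1), 1, 1), "degenerate")
  W <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  expect_error(fit_cox(W, 1:4, c(1, 1, 0, 1)), "rank deficient")
  # block naming when the block index is supplied
  blocks <- list(theta = 1L, gamma = list(Z1 = 2L), eta = integer(0))
  expect_error(
    fit_cox(W, 1:4, c(1, 1, 0, 1), blocks = blocks),
    "gamma\\[1\\]"
  )
})

test_that("permuting subjects leaves the estimate unchanged", {
  dat <- random_small_surv(8, 2, seed = 91)
  fit1 <- fit_cox(dat$W, dat$time, dat$event)
  set.seed(92)
  pi <- sample(8)
  fit2 <- fit_cox(dat$W[pi, ], dat$time[pi], dat$event[pi])
  expect_identical(fit1$coefficients, fit2$coefficients)
  expect_identical(fit1$loglik, fit2$loglik)
})

test_that("truncation-penalized AIC is simple arithmetic", {
  fake <- list(loglik = 0)
  expect_identical(aic_of_fit(fake, 0), 0)
  fake2 <- list(loglik = -12.5)
  expect_equal(aic_of_fit(fake2, 3) - aic_of_fit(fake2, 2), 2)
  expect_equal(aic_of_fit(fake2, 4), 2 * 4 + 25)
})
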