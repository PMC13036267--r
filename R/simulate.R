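#' True eigen-structure of the simulated functional covariate
#'
#' The simulated covariate is a Karhunen-Loeve series
#' \eqn{X(t) = \sum_j \xi_j \phi_j(t)} with independent
#' \eqn{\xi_j \sim N(0, \lambda_j)}, \eqn{\lambda_j = ((j-0.5)\pi)^{-2}}
#' and orthonormal \eqn{\phi_j(t) = \sqrt{2}\sin((j-0.5)\pi t)}.
#'
#' @param j Component index (vectorized).
#' @param t Evaluation points in `[0, 1]`.
#' @return `true_eigenvalue(j)` returns \eqn{\lambda_j};
#'   `true_eigenfunction(j, t)` returns \eqn{\phi_j} evaluated at `t`.
#' @export
true_eigenvalue <- function(j) ((j - 0.5) * pi)^-2

#' @rdname true_eigenvalue
#' @export
true_eigenfunction <- function(j, t) sqrt(2) * sin((j - 0.5) * pi * t)

#' True varying coefficients of the simulation design
#'
#' \eqn{\alpha_1(u) = 2\cos(2\pi u)} and, under the default reading,
#' \eqn{\alpha_2(u) = -2 + (3-u)^3/5}. The alternative reading
#' \eqn{-2 + (3-u)^{3/5}} is available via `form = "power_3_5"`.
#'
#' @param u Index values.
#' @param form Parse of the second coefficient: `"cubic_fifth"` (default)
#'   or `"power_3_5"`.
#' @return Numeric vector of coefficient values.
#' @export
true_alpha1 <- function(u) 2 * cos(2 * pi * u)

#' @rdname true_alpha1
#' @export
true_alpha2 <- function(u, form = c("cubic_fifth", "power_3_5")) {
  form <- match.arg(form)
  switch(form,
    cubic_fifth = -2 + (3 - u)^3 / 5,
    power_3_5 = -2 + (3 - u)^(3 / 5)
  )
}

#' True functional coefficient of the simulation design
#'
#' \eqn{\beta_0(t) = \sum_j \eta_{0j} \phi_j(t)} with loadings
#' `eta0 = c(1, 3)` by default, i.e.
#' \eqn{\beta_0(t) = \sqrt2\sin(\pi t/2) + 3\sqrt2\sin(3\pi t/2)}.
#'
#' @param t Evaluation points in `[0, 1]`.
#' @param eta0 Component loadings.
#' @return Numeric vector.
#' @export
true_beta <- function(t, eta0 = c(1, 3)) {
  drop(vapply(seq_along(eta0), function(j) true_eigenfunction(j, t),
    numeric(length(t))
  ) %*% eta0)
}

#' Simulation configuration
#'
#' Encodes the generating model of the simulation study: constant baseline
#' hazard \eqn{h_0 \equiv 1}, fixed coefficients
#' \eqn{\theta_0 = (1, 0.15, 0.35)}, varying coefficients [true_alpha1()]
#' and [true_alpha2()], functional coefficient loadings
#' \eqn{\eta_0 = (1, 3)}, and the Karhunen-Loeve covariate of
#' [true_eigenvalue()]. Censoring times are uniform on `(0, c)` with `c`
#' calibrated to the target censoring rate.
#'
#' Covariate laws: `U ~ Uniform(0,1)`, `Z1, Z2 ~ N(0,1)` and, under the
#' default `"gaussian"` law, `V1, V2, V3 ~ N(0,1)`, all independent.
#' `covariate_law = "bernoulli_v1"` switches `V1` to `Bernoulli(0.5)`.
#'
#' @param n Sample size (`>= 10`).
#' @param censor_rate Target censoring fraction in `(0, 1)`.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param grid_size Number of observation points of the functional
#'   covariate on `[0, 1]` (default 101).
#' @param kl_terms Number of Karhunen-Loeve terms kept in the generator
#'   (default 50; the omitted variance is below `2e-4` of the total).
#' @param theta0,eta0 True fixed coefficients and functional loadings.
#' @param alpha2_form Parse of the second varying coefficient, see
#'   [true_alpha2()].
#' @param covariate_law `"gaussian"` (default) or `"bernoulli_v1"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n, censor_rate = 0.1, seed = 1L,
                       grid_size = 101L, kl_terms = 50L,
                       theta0 = c(1, 0.15, 0.35), eta0 = c(1, 3),
                       alpha2_form = c("cubic_fifth", "power_3_5"),
                       covariate_law = c("gaussian", "bernoulli_v1")) {
  if (n < 10) stop_input("n must be at least 10")
  if (censor_rate <= 0 || censor_rate >= 1) {
    stop_input("censor_rate must be in (0, 1)")
  }
  if (kl_terms < length(eta0)) stop_input("kl_terms must cover all eta0 loadings")
  structure(
    list(
      n = as.integer(n), censor_rate = censor_rate, seed = as.integer(seed),
      grid_size = as.integer(grid_size), kl_terms = as.integer(kl_terms),
      theta0 = theta0, eta0 = eta0,
      alpha2_form = match.arg(alpha2_form),
      covariate_law = match.arg(covariate_law)
    ),
    class = "sim_config"
  )
}

#' Draw functional covariate curves
#'
#' Simulates `n` curves from the truncated Karhunen-Loeve series of the
#' study design on an equispaced grid over `[0, 1]`. The drawn component
#' scores are attached as the `"scores"` attribute (these are the *true*
#' scores used to form the hazard, as opposed to estimated ones).
#'
#' @param n Number of curves.
#' @param config A [sim_config()] (its `grid_size` and `kl_terms` are used).
#' @return A [functional_dataset()] with attribute `scores` (`n x kl_terms`).
#' @export
draw_functional <- function(n, config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- seq(0, 1, length.out = config$grid_size)
  J <- config$kl_terms
  lam <- true_eigenvalue(seq_len(J))
  xi <- matrix(stats::rnorm(n * J), n, J) %*% diag(sqrt(lam))
  Phi <- vapply(seq_len(J), function(j) true_eigenfunction(j, grid),
    numeric(length(grid))
  )
  fd <- functional_dataset(tcrossprod(xi, Phi), grid)
  attr(fd, "scores") <- xi
  fd
}

#' True linear predictor of the simulated hazard
#'
#' \eqn{lp_i = V_i^T\theta_0 + \alpha_1(U_i) Z_{i1} + \alpha_2(U_i) Z_{i2}
#' + \sum_j \xi_{ij}\eta_{0j}} using the *true* component scores.
#'
#' @param V,Z Covariate matrices.
#' @param U Index variable.
#' @param scores True component scores (`n x >= length(eta0)`).
#' @param config A [sim_config()].
#' @return Length-`n` numeric vector.
#' @export
linear_predictor <- function(V, Z, U, scores, config) {
  stopifnot(inherits(config, "sim_config"))
  V <- as.matrix(V)
  Z <- as.matrix(Z)
  scores <- as.matrix(scores)
  n <- nrow(V)
  if (nrow(Z) != n || length(U) != n || nrow(scores) != n) {
    stop_input("covariate shapes disagree")
  }
  k <- length(config$eta0)
  drop(V %*% config$theta0) +
    true_alpha1(U) * Z[, 1L] +
    true_alpha2(U, config$alpha2_form) * Z[, 2L] +
    drop(scores[, seq_len(k), drop = FALSE] %*% config$eta0)
}

#' Draw event times by cumulative-hazard inversion
#'
#' With constant baseline hazard \eqn{h_0 \equiv h_0^{(0)}}, the survival
#' time given linear predictor `lp` is exponential with rate
#' \eqn{h_0^{(0)} e^{lp}}; inverting the cumulative hazard gives
#' \eqn{T = -\log(U^*) / (h_0^{(0)} e^{lp})} with
#' \eqn{U^* \sim Uniform(0,1)}.
#'
#' @param lp Linear predictor vector.
#' @param h0 Constant baseline hazard level (default 1).
#' @return Vector of event times.
#' @export
draw_survival_times <- function(lp, h0 = 1) {
  if (h0 <= 0) stop_input("h0 must be positive")
  -log(stats::runif(length(lp))) / (h0 * exp(lp))
}

#' Calibrate the uniform censoring bound to a target rate
#'
#' Censoring times are `C ~ Uniform(0, c)`. Given the linear predictors,
#' the censoring probability has the closed form
#' \eqn{P(C < T) = mean[(1 - e^{-r c}) / (r c)]} with rates
#' \eqn{r_i = h_0 e^{lp_i}}; it decreases monotonically from 1 (as
#' `c -> 0`) to 0 (as `c -> Inf`), so the bound solving
#' `P(C < T) = target_rate` is found by root bracketing.
#'
#' @param lp_sample Linear predictors of a (large) calibration sample.
#' @param target_rate Desired censoring fraction in `(0, 1)`.
#' @param h0 Constant baseline hazard level.
#' @param tol Tolerance on the achieved rate.
#' @return The calibrated bound `c` (scalar).
#' @export
calibrate_censoring <- function(lp_sample, target_rate, h0 = 1, tol = 0.005) {
  if (target_rate <= 0 || target_rate >= 1) {
    stop_input("target_rate must be in (0, 1)")
  }
  r <- h0 * exp(lp_sample)
  check_finite(r, "exp(linear predictor)")
  p_cens <- function(cc) mean(-expm1(-r * cc) / (r * cc))
  lo <- 1e-8
  hi <- 1
  while (p_cens(hi) > target_rate && hi < 1e12) hi <- hi * 2
  if (p_cens(hi) > target_rate) stop_input("target censoring rate unattainable")
  root <- stats::uniroot(function(cc) p_cens(cc) - target_rate,
    lower = lo, upper = hi, tol = 1e-10
  )
  if (abs(p_cens(root$root) - target_rate) > tol) {
    stop_input("censoring calibration did not reach the target rate")
  }
  root$root
}

#' Simulate a complete survival dataset from the study design
#'
#' Draws covariates, the functional covariate, event times by
#' cumulative-hazard inversion, and uniform censoring calibrated to the
#' target rate; fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `fvc_sim` with elements
#'   `data` (tibble: `id`, `time`, `event`, `V1..V3`, `Z1`, `Z2`, `U`),
#'   `functional` (a [functional_dataset()]), and `truth` (generating
#'   parameters: `theta0`, `eta0`, the true scores, the linear predictor,
#'   the censoring bound and the seed).
#' @examples
#' sim <- simulate_dataset(sim_config(n = 50, censor_rate = 0.3, seed = 7))
#' mean(sim$data$event == 0) # close to 0.3
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  U <- stats::runif(n)
  Z <- matrix(stats::rnorm(n * 2L), n, 2L, dimnames = list(NULL, c("Z1", "Z2")))
  V <- matrix(stats::rnorm(n * 3L), n, 3L, dimnames = list(NULL, c("V1", "V2", "V3")))
  if (config$covariate_law == "bernoulli_v1") {
    V[, 1L] <- stats::rbinom(n, 1L, 0.5)
  }
  fd <- draw_functional(n, config)
  xi <- attr(fd, "scores")
  lp <- linear_predictor(V, Z, U, xi, config)
  T_true <- draw_survival_times(lp)
  cbound <- calibrate_censoring(lp, config$censor_rate)
  C <- stats::runif(n, 0, cbound)
  time <- pmin(T_true, C)
  event <- as.integer(T_true <= C)
  data <- tibble::tibble(
    id = seq_len(n), time = time, event = event,
    V1 = V[, 1L], V2 = V[, 2L], V3 = V[, 3L],
    Z1 = Z[, 1L], Z2 = Z[, 2L], U = U
  )
  structure(
    list(
      data = data,
      functional = fd,
      truth = list(
        theta0 = config$theta0, eta0 = config$eta0,
        alpha1 = true_alpha1, alpha2 = function(u) true_alpha2(u, config$alpha2_form),
        beta = function(t) true_beta(t, config$eta0),
        scores = xi, lp = lp, event_time = T_true,
        censor_bound = cbound, seed = config$seed
      ),
      config = config
    ),
    class = "fvc_sim"
  )
}

#' @export
print.fvc_sim <- function(x, ...) {
  cat("<fvc_sim> n = ", nrow(x$data),
    ", censoring target ", x$config$censor_rate,
    " (realized ", format(mean(x$data$event == 0), digits = 3),
    "), seed ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}
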