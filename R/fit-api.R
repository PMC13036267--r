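#' Configuration for the varying-coefficient functional Cox fit
#'
#' @param m_selection How to choose the number of retained functional
#'   principal components: `"aic"` (minimize `2m - 2 loglik` over
#'   `m_candidates`), `"pv"` (smallest `m` reaching `pv_threshold` of the
#'   variance), or `"fixed"` (use `m` as given; `m = 0` drops the functional
#'   block).
#' @param m Truncation used when `m_selection = "fixed"`.
#' @param pv_threshold Proportion-of-variance threshold in `(0, 1]`.
#' @param m_candidates Candidate truncations for AIC selection (default
#'   `1:min(10, available components)`).
#' @param kn Number of interior spline knots, or `"auto"` for
#'   [default_kn()].
#' @param order Spline order (default 4, cubic).
#' @param center_fpca Center curves before the covariance? Default `FALSE`
#'   (raw second-moment covariance).
#' @param u_domain Optional length-2 domain for the spline basis; defaults
#'   to the empirical range of `U` expanded by `1e-9` on each side.
#' @param tol,max_iter Newton convergence controls, see [fit_cox()].
#' @param eval_points Number of points for reconstructed coefficient curves.
#' @return A list of class `fvc_config`.
#' @export
fvc_config <- function(m_selection = c("aic", "pv", "fixed"),
                       m = NULL,
                       pv_threshold = 0.90,
                       m_candidates = NULL,
                       kn = "auto",
                       order = 4L,
                       center_fpca = FALSE,
                       u_domain = NULL,
                       tol = 1e-9,
                       max_iter = 100L,
                       eval_points = 200L) {
  m_selection <- match.arg(m_selection)
  if (m_selection == "fixed" && is.null(m)) {
    stop_input("m must be given when m_selection = 'fixed'")
  }
  if (pv_threshold <= 0 || pv_threshold > 1) {
    stop_input("pv_threshold must be in (0, 1]")
  }
  if (!is.null(m_candidates) && length(m_candidates) == 0L) {
    stop_input("m_candidates must be non-empty when given")
  }
  structure(
    list(
      m_selection = m_selection, m = m, pv_threshold = pv_threshold,
      m_candidates = m_candidates, kn = kn, order = as.integer(order),
      center_fpca = isTRUE(center_fpca), u_domain = u_domain,
      tol = tol, max_iter = as.integer(max_iter),
      eval_points = as.integer(eval_points)
    ),
    class = "fvc_config"
  )
}

# Infer covariate roles from column names of a per-subject data frame:
# V* -> fixed coefficients, Z* -> varying coefficients, U -> index variable.
collect_columns <- function(data, prefix) {
  nm <- grep(paste0("^", prefix, "[0-9]*$"), names(data), value = TRUE)
  nm <- nm[order(suppressWarnings(as.numeric(sub(prefix, "", nm))))]
  if (length(nm) == 0L) {
    return(NULL)
  }
  as.matrix(data[nm])
}

as_survival_dataset <- function(data, functional = NULL) {
  if (inherits(data, "survival_dataset")) {
    return(data)
  }
  data <- as.data.frame(data)
  for (col in c("time", "event")) {
    if (!col %in% names(data)) stop_input("data must have a '", col, "' column")
  }
  U <- if ("U" %in% names(data)) data$U else NULL
  survival_dataset(
    time = data$time, event = data$event,
    V = collect_columns(data, "V"), Z = collect_columns(data, "Z"),
    U = U, X = functional
  )
}

#' Fit the functional varying-coefficient Cox model
#'
#' Runs the full estimation pipeline: (1) functional principal component
#' analysis of the functional covariate and computation of subject scores;
#' (2) selection of the truncation `m`; (3) B-spline expansion of the
#' varying coefficients and maximization of the Cox log partial likelihood
#' over the expanded design. The estimated coefficient functions
#' \eqn{\hat\alpha_k(u) = \pi(u)^T\hat\gamma_k} and
#' \eqn{\hat\beta(t) = \sum_{j\le m}\hat\eta_j\hat\phi_j(t)} are
#' reconstructed on evaluation grids. The whole pipeline is deterministic
#' given the data and configuration.
#'
#' @param data Data frame with columns `time`, `event`, optional `V1, V2,
#'   ...` (fixed coefficients), `Z1, Z2, ...` (varying coefficients) and `U`
#'   (index variable); or a [survival_dataset()].
#' @param functional A [functional_dataset()] with one curve per row of
#'   `data` (optional when `m = 0` is forced).
#' @param config An [fvc_config()].
#' @return An object of class `fvc_cox_fit`.
#' @examples
#' sim <- simulate_dataset(sim_config(n = 150, censor_rate = 0.1, seed = 1))
#' fit <- fit_fvcox(sim$data, sim$functional,
#'   config = fvc_config(m_selection = "fixed", m = 2)
#' )
#' fit
#' @export
fit_fvcox <- function(data, functional = NULL, config = fvc_config()) {
  stopifnot(inherits(config, "fvc_config"))
  sd <- tryCatch(as_survival_dataset(data, functional),
    error = function(e) stop_input(conditionMessage(e), stage = "input")
  )
  p1 <- ncol(sd$V)
  p <- ncol(sd$Z)
  n <- sd$n

  # Step 1/2: FPCA of the functional covariate and truncation selection
  fp <- NULL
  if (!is.null(sd$X)) {
    fp <- tryCatch(fpca(sd$X, center = config$center_fpca),
      error = function(e) stop_input(conditionMessage(e), stage = "fpca")
    )
  }
  J <- if (is.null(fp)) 0L else ncol(fp$scores)

  spec <- NULL
  if (p > 0L) {
    kn <- if (identical(config$kn, "auto")) default_kn(n) else as.integer(config$kn)
    dom <- config$u_domain
    if (is.null(dom)) dom <- range(sd$U) + c(-1e-9, 1e-9)
    spec <- tryCatch(spline_spec(kn, config$order, dom),
      error = function(e) stop_input(conditionMessage(e), stage = "splines")
    )
  }

  fit_m <- function(m) {
    des <- build_design(sd, spec, fp, m)
    fit <- fit_cox(des$W, sd$time, sd$event,
      tol = config$tol, max_iter = config$max_iter, blocks = des$block_index
    )
    list(design = des, fit = fit, loglik = fit$loglik, converged = fit$converged)
  }

  m <- switch(config$m_selection,
    fixed = as.integer(config$m),
    pv = {
      if (is.null(fp)) stop_input("pv selection needs a functional covariate", stage = "fpca")
      select_m_pv(fp$eigenvalues, config$pv_threshold)
    },
    aic = {
      if (is.null(fp)) stop_input("aic selection needs a functional covariate", stage = "fpca")
      cand <- config$m_candidates
      if (is.null(cand)) cand <- seq_len(min(10L, J))
      select_m_aic(cand, function(mm) fit_m(mm))
    }
  )
  if (m > J) stop_input("m = ", m, " exceeds available components (", J, ")", stage = "fpca")

  # Step 3: maximize the log partial likelihood over the expanded design
  res <- tryCatch(fit_m(m),
    error = function(e) stop_input(conditionMessage(e), stage = "cox")
  )
  fit <- res$fit
  des <- res$design
  blocks <- des$block_index

  eval_u <- if (p > 0L) {
    seq(spec$domain[1L], spec$domain[2L], length.out = config$eval_points)
  } else {
    NULL
  }
  alpha <- if (p > 0L) {
    gam <- fit$coefficients[unlist(blocks$gamma)]
    reconstruct_alpha(gam, spec, eval_u)
  } else {
    list()
  }
  beta <- if (m > 0L) {
    eta <- fit$coefficients[blocks$eta]
    reconstruct_beta(eta, fp, seq(0, 1, length.out = config$eval_points))
  } else {
    NULL
  }

  structure(
    list(
      coefficients = fit$coefficients,
      se = fit$se,
      block_index = blocks,
      theta = fit$coefficients[blocks$theta],
      gamma = fit$coefficients[unlist(blocks$gamma)],
      eta = fit$coefficients[blocks$eta],
      loglik = fit$loglik,
      aic = aic_of_fit(fit, m),
      aic_full = 2 * length(fit$coefficients) - 2 * fit$loglik,
      m = m,
      spec = spec,
      fpca = fp,
      alpha = alpha,
      beta = beta,
      converged = fit$converged,
      monotone_likelihood = fit$monotone_likelihood,
      n_iter = fit$n_iter,
      n = n,
      n_events = sum(sd$event),
      config = config
    ),
    class = "fvc_cox_fit"
  )
}

#' @export
print.fvc_cox_fit <- function(x, ...) {
  cat("Functional varying-coefficient Cox fit\n")
  cat(
    "  n = ", x$n, ", events = ", x$n_events, ", m = ", x$m,
    if (!is.null(x$spec)) {
      paste0(
        ", spline order ", x$spec$order, " with ",
        x$spec$n_interior_knots, " interior knots"
      )
    } else {
      ""
    }, "\n",
    sep = ""
  )
  cat(
    "  loglik = ", format(x$loglik), ", AIC(m) = ", format(x$aic),
    if (!x$converged) "  [NOT converged]" else "", "\n",
    sep = ""
  )
  if (length(x$theta)) {
    cat("  theta:\n")
    print(round(rbind(estimate = x$theta, se = x$se[x$block_index$theta]), 4))
  }
  if (length(x$eta)) {
    cat("  eta (functional component loadings):\n")
    print(round(rbind(estimate = x$eta, se = x$se[x$block_index$eta]), 4))
  }
  invisible(x)
}

#' Reconstruct the functional coefficient from component loadings
#'
#' Evaluates \eqn{\hat\beta(t) = \sum_{j\le m}\hat\eta_j \hat\phi_j(t)} on
#' `eval_grid`, interpolating the grid-sampled eigenfunctions linearly.
#'
#' @param eta_hat Estimated loadings, one per retained component.
#' @param fpca An `fpca_result`.
#' @param eval_grid Evaluation points inside `[0, 1]`.
#' @return A `function_estimate` tibble with columns `grid` and `value`.
#' @export
reconstruct_beta <- function(eta_hat, fpca, eval_grid = seq(0, 1, length.out = 200)) {
  stopifnot(inherits(fpca, "fpca_result"))
  m <- length(eta_hat)
  if (m > ncol(fpca$eigenfunctions)) {
    stop_input("eta_hat has more entries than available components")
  }
  if (any(eval_grid < 0 | eval_grid > 1)) {
    stop_input("eval_grid must lie within [0, 1]")
  }
  vals <- numeric(length(eval_grid))
  if (m > 0L) {
    Phi <- vapply(
      seq_len(m),
      function(j) {
        stats::approx(fpca$grid, fpca$eigenfunctions[, j],
          xout = eval_grid, rule = 2
        )$y
      },
      numeric(length(eval_grid))
    )
    vals <- drop(matrix(Phi, ncol = m) %*% eta_hat)
  }
  function_estimate(eval_grid, vals, name = "beta")
}

#' Reconstruct varying coefficients from spline coefficients
#'
#' Evaluates \eqn{\hat\alpha_k(u) = \pi(u)^T\hat\gamma_k} for each
#' varying-coefficient covariate `k` on `eval_grid`.
#'
#' @param gamma_hat Concatenated spline coefficients, `p * basis_dim`
#'   entries grouped by covariate.
#' @param spec The [spline_spec()] used in the fit.
#' @param eval_grid Evaluation points inside the spline domain.
#' @return A list of `function_estimate` tibbles, one per covariate.
#' @export
reconstruct_alpha <- function(gamma_hat, spec, eval_grid = NULL) {
  stopifnot(inherits(spec, "spline_spec"))
  q <- spec$basis_dim
  if (length(gamma_hat) %% q != 0L) {
    stop_input("length(gamma_hat) must be a multiple of the basis dimension ", q)
  }
  p <- length(gamma_hat) %/% q
  if (is.null(eval_grid)) {
    eval_grid <- seq(spec$domain[1L], spec$domain[2L], length.out = 200L)
  }
  B <- basis_matrix(eval_grid, spec)
  lapply(seq_len(p), function(k) {
    gk <- gamma_hat[(k - 1L) * q + seq_len(q)]
    function_estimate(eval_grid, drop(B %*% gk), name = paste0("alpha", k))
  })
}

#' Tibble container for an estimated coefficient function
#'
#' @param grid Evaluation points.
#' @param value Estimated function values (finite).
#' @param name Label for the function (used in plots).
#' @return A tibble of class `function_estimate` with columns `grid`,
#'   `value`.
#' @export
function_estimate <- function(grid, value, name = "f") {
  check_finite(value, "function values")
  out <- tibble::tibble(grid = as.numeric(grid), value = as.numeric(value))
  attr(out, "fn_name") <- name
  class(out) <- c("function_estimate", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a varying-coefficient functional Cox fit
#'
#' @param x An `fvc_cox_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `block`,
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.fvc_cox_fit <- function(x, ...) {
  blocks <- x$block_index
  block_of <- character(length(x$coefficients))
  block_of[blocks$theta] <- "theta"
  for (k in seq_along(blocks$gamma)) {
    block_of[blocks$gamma[[k]]] <- paste0("gamma[", names(blocks$gamma)[k], "]")
  }
  block_of[blocks$eta] <- "eta"
  stat <- x$coefficients / x$se
  tibble::tibble(
    term = names(x$coefficients),
    block = block_of,
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
}

#' One-row model summary of a varying-coefficient functional Cox fit
#'
#' @param x An `fvc_cox_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, truncation, spline settings,
#'   log partial likelihood and both AIC flavours.
#' @export
glance.fvc_cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    m = x$m,
    kn = if (is.null(x$spec)) NA_integer_ else x$spec$n_interior_knots,
    spline_order = if (is.null(x$spec)) NA_integer_ else x$spec$order,
    loglik = x$loglik,
    aic = x$aic,
    aic_full = x$aic_full,
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Plot the estimated coefficient functions of a fit
#'
#' Draws the reconstructed varying coefficients \eqn{\hat\alpha_k(u)} and
#' (when present) the functional coefficient \eqn{\hat\beta(t)} as line
#' panels.
#'
#' @param object An `fvc_cox_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fvc_cox_fit <- function(object, ...) {
  curves <- object$alpha
  if (!is.null(object$beta)) curves <- c(curves, list(object$beta))
  if (length(curves) == 0L) stop_input("fit has no coefficient functions to plot")
  df <- purrr::map_dfr(curves, function(fe) {
    tibble::tibble(
      fn = attr(fe, "fn_name"),
      grid = fe$grid, value = fe$value
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fn, scales = "free") +
    ggplot2::labs(x = "argument", y = "estimate")
}

#' @export
autoplot.function_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "argument", y = attr(object, "fn_name"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
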