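#' Construct a survival dataset for the varying-coefficient functional Cox model
#'
#' Bundles per-subject observed times, event indicators, fixed-coefficient
#' covariates `V`, varying-coefficient covariates `Z`, the index variable `U`
#' driving the varying coefficients, and (optionally) the functional
#' covariate.
#'
#' @param time Positive observed times (event or censoring).
#' @param event 0/1 event indicators; at least one event required.
#' @param V `n x p1` matrix of fixed-coefficient covariates (may have 0
#'   columns).
#' @param Z `n x p` matrix of varying-coefficient covariates (may have 0
#'   columns).
#' @param U Length-`n` index variable (e.g. age).
#' @param X Optional [functional_dataset()] with `n` curves.
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(time, event, V = NULL, Z = NULL, U = NULL, X = NULL) {
  time <- as.numeric(time)
  n <- length(time)
  check_finite(time, "time")
  if (any(time <= 0)) stop_input("times must be positive")
  event <- as.integer(event)
  if (length(event) != n || !all(event %in% c(0L, 1L))) {
    stop_input("event must be a 0/1 vector matching time")
  }
  if (sum(event) < 1L) stop_input("need at least one observed event")
  as_mat <- function(x, name) {
    if (is.null(x)) {
      return(matrix(numeric(0), n, 0))
    }
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != n) stop_input(name, " must have ", n, " rows")
    check_finite(x, name)
    x
  }
  V <- as_mat(V, "V")
  Z <- as_mat(Z, "Z")
  if (ncol(Z) > 0L) {
    if (is.null(U)) stop_input("U is required when Z has columns")
    U <- as.numeric(U)
    if (length(U) != n) stop_input("U must have length ", n)
    check_finite(U, "U")
  } else {
    U <- if (is.null(U)) rep(NA_real_, n) else as.numeric(U)
  }
  if (!is.null(X)) {
    stopifnot(inherits(X, "functional_dataset"))
    if (nrow(X$values) != n) stop_input("X must contain ", n, " curves")
  }
  structure(
    list(time = time, event = event, V = V, Z = Z, U = U, X = X, n = n),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> n = ", x$n, ", events = ", sum(x$event),
    ", p1 = ", ncol(x$V), ", p = ", ncol(x$Z),
    if (!is.null(x$X)) ", with functional covariate" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Build the expanded design matrix
#'
#' Expands the model's linear predictor into a finite-dimensional design:
#' the fixed-coefficient block `V`, one block per varying-coefficient
#' covariate with columns \eqn{Z_{ik} B_j(U_i)} (spline basis evaluated at
#' the index variable), and the leading `m` functional principal component
#' scores.
#'
#' @param data A [survival_dataset()].
#' @param spec A [spline_spec()] for the varying-coefficient expansion
#'   (required when `Z` has columns).
#' @param fpca An `fpca_result` with scores (required when `m > 0`).
#' @param m Number of retained component scores.
#' @return An object of class `design_expansion`: list with the design matrix
#'   `W`, `block_index` (named column index sets), `spec`, `fpca` and `m`.
#' @export
build_design <- function(data, spec = NULL, fpca = NULL, m = 0L) {
  stopifnot(inherits(data, "survival_dataset"))
  m <- as.integer(m)
  p1 <- ncol(data$V)
  p <- ncol(data$Z)
  blocks <- list()
  cols <- list()
  pos <- 0L
  if (p1 > 0L) {
    vn <- colnames(data$V)
    if (is.null(vn)) vn <- paste0("V", seq_len(p1))
    cols$theta <- data$V
    colnames(cols$theta) <- vn
    blocks$theta <- pos + seq_len(p1)
    pos <- pos + p1
  } else {
    blocks$theta <- integer(0)
  }
  blocks$gamma <- vector("list", p)
  if (p > 0L) {
    stopifnot(inherits(spec, "spline_spec"))
    B <- basis_matrix(data$U, spec)
    zn <- colnames(data$Z)
    if (is.null(zn)) zn <- paste0("Z", seq_len(p))
    for (k in seq_len(p)) {
      blk <- data$Z[, k] * B
      colnames(blk) <- paste0(zn[k], ":B", seq_len(spec$basis_dim))
      cols[[paste0("gamma", k)]] <- blk
      blocks$gamma[[k]] <- pos + seq_len(spec$basis_dim)
      pos <- pos + spec$basis_dim
    }
    names(blocks$gamma) <- zn
  }
  if (m > 0L) {
    stopifnot(inherits(fpca, "fpca_result"))
    if (is.null(fpca$scores)) stop_input("fpca result has no scores")
    if (m > ncol(fpca$scores)) {
      stop_input("m = ", m, " exceeds the ", ncol(fpca$scores), " available components")
    }
    if (nrow(fpca$scores) != data$n) stop_input("score rows must match subjects")
    sc <- fpca$scores[, seq_len(m), drop = FALSE]
    colnames(sc) <- paste0("xi", seq_len(m))
    cols$eta <- sc
    blocks$eta <- pos + seq_len(m)
    pos <- pos + m
  } else {
    blocks$eta <- integer(0)
  }
  W <- do.call(cbind, cols)
  if (is.null(W)) W <- matrix(numeric(0), data$n, 0)
  check_finite(W, "design matrix")
  structure(
    list(W = W, block_index = blocks, spec = spec, fpca = fpca, m = m),
    class = "design_expansion"
  )
}

# Risk-set cumulative sums shared by value/gradient/Hessian.
# Subjects are sorted by decreasing time so that the risk set
# R(t_i) = {j : t_j >= t_i} is a prefix; tied times share the full
# tied-group denominator (Breslow), which reduces to the distinct-time
# formula when there are no ties.
cox_parts <- function(delta, W, time, event) {
  n <- length(time)
  ord <- order(time, decreasing = TRUE)
  Ws <- W[ord, , drop = FALSE]
  ev <- event[ord] == 1L
  ts <- time[ord]
  lp <- drop(Ws %*% delta)
  M <- max(lp)
  e <- exp(lp - M)
  r <- rle(ts)
  denom_idx <- rep.int(cumsum(r$lengths), r$lengths)
  list(
    Ws = Ws, ev = ev, lp = lp, M = M, e = e,
    S0 = cumsum(e), di = denom_idx
  )
}

#' Negative log partial likelihood with derivatives
#'
#' Evaluates \eqn{-Q(\delta)} for the Cox partial likelihood
#' \eqn{Q(\delta)=\sum_{i:\delta_i=1}[w_i^T\delta - \log\sum_{j\in R(\tilde
#' T_i)} e^{w_j^T\delta}]} with risk sets \eqn{R(t)=\{j:\tilde T_j\ge t\}},
#' together with its exact gradient and Hessian. Tied event times fall back
#' to Breslow's approximation (identical to the formula above when times are
#' distinct). The log-sum-exp is max-guarded against overflow.
#'
#' @param delta Coefficient vector.
#' @param W Design matrix (`n x d`).
#' @param time,event Observed times and 0/1 event indicators.
#' @param what Which pieces to compute, a subset of
#'   `c("value", "gradient", "hessian")`.
#' @return List with requested elements `value` (scalar), `gradient`
#'   (length `d`) and `hessian` (`d x d`, positive semidefinite).
#' @export
neg_log_partial_likelihood <- function(delta, W, time, event,
                                       what = c("value", "gradient", "hessian")) {
  W <- as.matrix(W)
  d <- ncol(W)
  if (length(delta) != d) stop_input("delta must have length ncol(W)")
  if (nrow(W) != length(time) || length(time) != length(event)) {
    stop_input("dimensions of W, time and event disagree")
  }
  what <- match.arg(what, several.ok = TRUE)
  p <- cox_parts(delta, W, time, event)
  Ei <- p$di[p$ev] # denominator index for each event
  out <- list()
  if ("value" %in% what) {
    out$value <- -sum((p$lp[p$ev] - p$M) - log(p$S0[Ei]))
  }
  if (any(c("gradient", "hessian") %in% what) && d > 0L) {
    S1 <- apply(p$e * p$Ws, 2L, cumsum)
    if (length(p$e) == 1L) S1 <- matrix(S1, 1L)
    Vbar <- S1[Ei, , drop = FALSE] / p$S0[Ei]
    if ("gradient" %in% what) {
      out$gradient <- -colSums(p$Ws[p$ev, , drop = FALSE] - Vbar)
    }
    if ("hessian" %in% what) {
      WW <- p$Ws[, rep(seq_len(d), d), drop = FALSE] *
        p$Ws[, rep(seq_len(d), each = d), drop = FALSE]
      S2 <- apply(p$e * WW, 2L, cumsum)
      if (length(p$e) == 1L) S2 <- matrix(S2, 1L)
      A <- matrix(colSums(S2[Ei, , drop = FALSE] / p$S0[Ei]), d, d)
      H <- A - crossprod(Vbar)
      out$hessian <- (H + t(H)) / 2
    }
  } else if (d == 0L) {
    if ("gradient" %in% what) out$gradient <- numeric(0)
    if ("hessian" %in% what) out$hessian <- matrix(numeric(0), 0, 0)
  }
  out
}

#' Maximize the Cox log partial likelihood by Newton-Raphson
#'
#' Newton iterations with step-halving on the negative log partial
#' likelihood, starting from `init` (zero by default; the objective is
#' convex). Convergence is declared when the objective change drops below
#' `tol` or the gradient sup-norm drops below `1e-6`. A monotone-likelihood
#' (separation) failure is flagged — not raised — when the coefficient
#' sup-norm exceeds 50 while the likelihood still improves. Standard errors
#' come from the inverse observed information at the maximum.
#'
#' @param W Design matrix, full column rank.
#' @param time,event Observed times and 0/1 indicators (at least one event).
#' @param init Optional starting value (default all zeros).
#' @param tol Convergence tolerance on the objective change.
#' @param max_iter Iteration cap; hitting it yields `converged = FALSE`.
#' @param blocks Optional `block_index` (from [build_design()]) used to name
#'   the offending block when the information matrix is singular.
#' @return An object of class `cox_newton_fit`: list with `coefficients`,
#'   `se`, `loglik` (maximized \eqn{Q}), `n_iter`, `converged`,
#'   `monotone_likelihood`, `gradient_norm` and `information`.
#' @export
fit_cox <- function(W, time, event, init = NULL, tol = 1e-9, max_iter = 100L,
                    blocks = NULL) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  n <- nrow(W)
  d <- ncol(W)
  event <- as.integer(event)
  if (sum(event) < 1L || n < 2L) {
    stop_input("degenerate data: need at least 2 subjects and 1 event")
  }
  if (d > 0L) {
    qr_W <- qr(W)
    if (qr_W$rank < d) {
      bad <- sort(qr_W$pivot[seq.int(qr_W$rank + 1L, d)])
      lbl <- colnames(W)[bad]
      if (is.null(lbl)) lbl <- paste0("column ", bad)
      blk <- ""
      if (!is.null(blocks)) {
        in_block <- function(idx) {
          if (any(bad %in% blocks$theta)) {
            return("theta")
          }
          for (k in seq_along(blocks$gamma)) {
            if (any(bad %in% blocks$gamma[[k]])) {
              return(paste0("gamma[", k, "]"))
            }
          }
          if (any(bad %in% blocks$eta)) {
            return("eta")
          }
          "unknown"
        }
        blk <- paste0(" in block ", in_block(bad))
      }
      stop_input(
        "design matrix is rank deficient (singular information): ",
        paste(lbl, collapse = ", "), blk
      )
    }
  }
  delta <- if (is.null(init)) numeric(d) else as.numeric(init)
  if (length(delta) != d) stop_input("init must have length ncol(W)")
  f <- neg_log_partial_likelihood(delta, W, time, event)
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  while (iter < max_iter && d > 0L) {
    iter <- iter + 1L
    step <- tryCatch(solve(f$hessian, f$gradient), error = function(e) e)
    if (inherits(step, "error")) {
      stop_input("information matrix is numerically singular at iteration ", iter)
    }
    size <- 1
    repeat {
      cand <- delta - size * step
      fc <- neg_log_partial_likelihood(cand, W, time, event, what = "value")
      if (fc$value <= f$value + 1e-12 || size < 2^-30) break
      size <- size / 2
    }
    dval <- f$value - fc$value
    delta <- cand
    f <- neg_log_partial_likelihood(delta, W, time, event)
    if (abs(dval) < tol || max(abs(f$gradient)) < 1e-6) {
      # a flat objective with a persistently large Newton step far from the
      # origin is monotone-likelihood divergence, not convergence
      if (max(abs(step)) > 0.5 && max(abs(delta)) > 10) {
        monotone <- TRUE
      } else {
        converged <- TRUE
      }
      break
    }
    if (max(abs(delta)) > 50 && dval > tol) {
      monotone <- TRUE
      break
    }
  }
  if (d == 0L) converged <- TRUE
  se <- rep(NA_real_, d)
  if (d > 0L && !monotone) {
    inv <- tryCatch(solve(f$hessian), error = function(e) NULL)
    if (!is.null(inv)) {
      dg <- diag(inv)
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }
  names(delta) <- colnames(W)
  names(se) <- colnames(W)
  structure(
    list(
      coefficients = delta,
      se = se,
      loglik = -f$value,
      n_iter = iter,
      converged = converged && !monotone,
      monotone_likelihood = monotone,
      gradient_norm = if (d > 0L) max(abs(f$gradient)) else 0,
      information = if (d > 0L) f$hessian else matrix(numeric(0), 0, 0),
      n = n,
      n_events = sum(event)
    ),
    class = "cox_newton_fit"
  )
}

#' @export
print.cox_newton_fit <- function(x, ...) {
  cat("<cox_newton_fit> n = ", x$n, ", events = ", x$n_events,
    ", loglik = ", format(x$loglik),
    if (x$converged) ", converged" else ", NOT converged",
    if (x$monotone_likelihood) " (monotone likelihood)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Truncation-penalized AIC of a fit
#'
#' `AIC(m) = 2m - 2 loglik`, penalizing only the number of retained
#' functional components `m` — the criterion used to select the truncation.
#' For a conventional all-parameter AIC use `2 * length(coef) - 2 * loglik`
#' (reported as `aic_full` by [fit_fvcox()]).
#'
#' @param fit A `cox_newton_fit` (or any object with a `loglik` field).
#' @param m Truncation number.
#' @return Numeric AIC value.
#' @export
aic_of_fit <- function(fit, m) {
  2 * m - 2 * fit$loglik
}
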