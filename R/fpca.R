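#' Construct a functional dataset
#'
#' Bundles `n` curves observed on a shared, strictly increasing grid in
#' `[0, 1]`. This is the container for the functional covariate \eqn{X_i(t)}
#' entering the hazard through \eqn{\int_0^1 X_i(t)\beta(t)\,dt}.
#'
#' @param values Numeric matrix (or data frame) with one row per subject and
#'   one column per grid point.
#' @param grid Strictly increasing numeric vector of observation points in
#'   `[0, 1]`, one per column of `values`.
#' @param subject_ids Optional identifier vector (default `1:n`).
#' @return An object of class `functional_dataset` with fields `grid`,
#'   `values` and `subject_ids`.
#' @examples
#' g <- seq(0, 1, length.out = 21)
#' fd <- functional_dataset(rbind(sin(pi * g), cos(pi * g)), g)
#' fd
#' @export
functional_dataset <- function(values, grid, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  grid <- as.numeric(grid)
  G <- length(grid)
  if (G < 4L) stop_input("grid needs at least 4 points")
  if (ncol(values) != G) {
    stop_input("ncol(values) = ", ncol(values), " but grid has ", G, " points")
  }
  if (nrow(values) < 2L) stop_input("need at least 2 curves")
  if (any(diff(grid) <= 0)) stop_input("grid must be strictly increasing")
  if (grid[1L] < 0 || grid[G] > 1) stop_input("grid must lie within [0, 1]")
  check_finite(grid, "grid")
  check_finite(values, "values")
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(values))
  if (length(subject_ids) != nrow(values)) {
    stop_input("subject_ids length must equal the number of curves")
  }
  structure(
    list(grid = grid, values = values, subject_ids = subject_ids),
    class = "functional_dataset"
  )
}

#' @export
print.functional_dataset <- function(x, ...) {
  cat(
    "<functional_dataset> ", nrow(x$values), " curves on ",
    length(x$grid), " grid points in [",
    format(x$grid[1L]), ", ", format(x$grid[length(x$grid)]), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Empirical covariance of a functional dataset
#'
#' Computes the empirical covariance surface
#' \eqn{\hat K(s,t) = n^{-1}\sum_i X_i(s) X_i(t)} on the observation grid.
#' By default the curves are not mean-centered, matching the raw
#' second-moment definition; set `center = TRUE` to subtract the pointwise
#' sample mean first (the two agree asymptotically for zero-mean processes).
#'
#' @param data A [functional_dataset()].
#' @param center Logical; subtract the pointwise mean curve first?
#' @return A `G x G` symmetric numeric matrix.
#' @examples
#' g <- seq(0, 1, length.out = 21)
#' fd <- functional_dataset(rbind(sin(pi * g), -sin(pi * g)), g)
#' K <- empirical_covariance(fd)
#' @export
empirical_covariance <- function(data, center = FALSE) {
  stopifnot(inherits(data, "functional_dataset"))
  X <- data$values
  if (center) X <- sweep(X, 2L, colMeans(X))
  crossprod(X) / nrow(X)
}

#' Eigendecompose a covariance surface into L2-orthonormal components
#'
#' Solves the quadrature-weighted eigenproblem for a covariance surface
#' sampled on a grid: with trapezoid weights `w`, the symmetric problem
#' \eqn{W^{1/2} K W^{1/2}} is decomposed and eigenvectors are rescaled by
#' \eqn{W^{-1/2}}, so the returned eigenfunctions are orthonormal under the
#' L2 inner product \eqn{\int \phi_j \phi_k = \delta_{jk}} (trapezoid
#' quadrature), not the Euclidean one.
#'
#' Eigenvalues are clipped to zero below numerical noise and components with
#' eigenvalue below `1e-10` times the leading one are dropped. Each
#' eigenfunction's sign is fixed so that \eqn{\int \phi_j(t)\,dt \ge 0};
#' when that integral is numerically zero, the first grid point where
#' \eqn{|\phi_j|} exceeds tolerance is made positive. Without such a
#' convention the component scores are not comparable across replications.
#'
#' @param K Symmetric `G x G` covariance matrix sampled on `grid`.
#' @param grid The observation grid (strictly increasing, in `[0, 1]`).
#' @return An object of class `fpca_result` with `eigenvalues` (non-increasing),
#'   `eigenfunctions` (`G x J` matrix, one component per column), `grid`, and
#'   `pv` (cumulative proportion of variance). Scores are not attached; see
#'   [compute_scores()].
#' @export
eigendecompose <- function(K, grid) {
  K <- as.matrix(K)
  grid <- as.numeric(grid)
  G <- length(grid)
  if (!isTRUE(nrow(K) == G && ncol(K) == G)) {
    stop_input("K must be ", G, " x ", G, " to match the grid")
  }
  check_finite(K, "K")
  sym_err <- max(abs(K - t(K)))
  if (sym_err > 1e-8 * max(1, max(abs(K)))) {
    stop_input("K is not symmetric (max asymmetry ", format(sym_err), ")")
  }
  K <- (K + t(K)) / 2
  w <- trapezoid_weights(grid)
  sw <- sqrt(w)
  B <- K * tcrossprod(sw)
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values
  lam_tol <- 1e-10 * max(abs(lam), .Machine$double.eps)
  lam[lam < 0 & lam > -lam_tol] <- 0
  lam[lam < 0] <- 0 # covariance input: residual negatives are roundoff
  keep <- if (lam[1L] > 0) which(lam > 1e-10 * lam[1L]) else integer(0)
  phi <- e$vectors[, keep, drop = FALSE] / sw
  lam_keep <- lam[keep]
  # sign convention
  for (j in seq_along(lam_keep)) {
    s <- sum(w * phi[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) phi[, j] <- -phi[, j]
    } else {
      k <- which(abs(phi[, j]) > 1e-8)[1L]
      if (!is.na(k) && phi[k, j] < 0) phi[, j] <- -phi[, j]
    }
  }
  total <- sum(lam)
  structure(
    list(
      eigenvalues = lam_keep,
      eigenfunctions = phi,
      grid = grid,
      scores = NULL,
      m = NULL,
      pv = if (total > 0) cumsum(lam_keep) / total else rep(NA_real_, length(lam_keep))
    ),
    class = "fpca_result"
  )
}

#' @export
print.fpca_result <- function(x, ...) {
  J <- length(x$eigenvalues)
  cat("<fpca_result> ", J, " components",
    if (!is.null(x$m)) paste0(", m = ", x$m) else "", "\n",
    sep = ""
  )
  if (J > 0L) {
    k <- min(J, 5L)
    cat(
      "  leading eigenvalues:",
      paste(signif(x$eigenvalues[seq_len(k)], 4), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Project curves on estimated eigenfunctions
#'
#' Computes the component scores \eqn{\hat\xi_{ij} = \int X_i(t)
#' \hat\phi_j(t)\,dt} by trapezoid quadrature on the shared grid.
#'
#' @param data A [functional_dataset()].
#' @param fpca An `fpca_result` computed on the same grid.
#' @return An `n x J` matrix of scores.
#' @export
compute_scores <- function(data, fpca) {
  stopifnot(inherits(data, "functional_dataset"), inherits(fpca, "fpca_result"))
  if (length(data$grid) != length(fpca$grid) ||
    max(abs(data$grid - fpca$grid)) > 1e-12) {
    stop_input("grid of data and fpca result differ")
  }
  w <- trapezoid_weights(data$grid)
  data$values %*% (fpca$eigenfunctions * w)
}

#' Functional principal component analysis
#'
#' One-stop FPCA: empirical covariance, quadrature-weighted
#' eigendecomposition and score computation.
#'
#' @inheritParams empirical_covariance
#' @return An `fpca_result` with `scores` attached.
#' @examples
#' g <- seq(0, 1, length.out = 51)
#' set.seed(1)
#' X <- t(replicate(30, rnorm(1) * sqrt(2) * sin(pi * g / 2)))
#' fp <- fpca(functional_dataset(X, g))
#' fp$eigenvalues[1]
#' @export
fpca <- function(data, center = FALSE) {
  K <- empirical_covariance(data, center = center)
  out <- eigendecompose(K, data$grid)
  out$scores <- compute_scores(data, out)
  out
}

#' Select the truncation by proportion of variance
#'
#' Returns the smallest `m` whose leading eigenvalues account for at least
#' `threshold` of the total variance, i.e. the smallest `m` with
#' \eqn{PV(m) = \sum_{j\le m}\lambda_j / \sum_j \lambda_j \ge} `threshold`.
#'
#' @param eigenvalues Non-negative, non-increasing numeric vector.
#' @param threshold Fraction in `(0, 1]` (e.g. `0.90` or `0.95`).
#' @return Integer truncation `m`.
#' @examples
#' select_m_pv(c(4, 3, 2, 1), 0.90) # 3
#' @export
select_m_pv <- function(eigenvalues, threshold = 0.90) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
    threshold <= 0 || threshold > 1) {
    stop_input("threshold must be in (0, 1]")
  }
  if (any(eigenvalues < 0)) stop_input("eigenvalues must be non-negative")
  total <- sum(eigenvalues)
  if (total <= 0) stop_input("all eigenvalues are zero; no variance to truncate")
  pv <- cumsum(eigenvalues) / total
  as.integer(which(pv >= threshold - 1e-12)[1L])
}

#' Select the truncation by AIC
#'
#' Evaluates `AIC(m) = 2m - 2 * loglik(m)` over a candidate set, where
#' `loglik(m)` is the maximized log partial likelihood of the model fitted
#' with `m` retained components, and returns the minimizer (ties broken
#' toward the smaller `m`). Candidates whose fit fails are skipped with a
#' warning.
#'
#' @param candidate_ms Integer vector of candidate truncations.
#' @param fit_function Function taking one candidate `m` and returning either
#'   a number (the maximized log partial likelihood) or a list with a
#'   `loglik` field.
#' @return The selected `m` (integer).
#' @export
select_m_aic <- function(candidate_ms, fit_function) {
  candidate_ms <- sort(unique(as.integer(candidate_ms)))
  if (length(candidate_ms) == 0L) stop_input("candidate_ms is empty")
  aics <- rep(NA_real_, length(candidate_ms))
  for (i in seq_along(candidate_ms)) {
    m <- candidate_ms[i]
    res <- tryCatch(fit_function(m), error = function(e) e)
    if (inherits(res, "error")) {
      warning("candidate m = ", m, " skipped: ", conditionMessage(res),
        call. = FALSE
      )
      next
    }
    ll <- if (is.list(res)) res$loglik else res
    if (is.list(res) && !is.null(res$converged) && !isTRUE(res$converged)) {
      warning("candidate m = ", m, " skipped: fit did not converge",
        call. = FALSE
      )
      next
    }
    aics[i] <- 2 * m - 2 * ll
  }
  if (all(is.na(aics))) stop_input("all candidate truncations failed to fit")
  candidate_ms[which.min(aics)]
}
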