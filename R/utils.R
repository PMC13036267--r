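#' Trapezoidal quadrature weights for a (possibly irregular) grid
#'
#' Weights `w` such that `sum(w * f(grid))` approximates the integral of `f`
#' over `[min(grid), max(grid)]`.
#'
#' @param grid Strictly increasing numeric vector.
#' @return Numeric vector of weights, same length as `grid`.
#' @keywords internal
#' @noRd
trapezoid_weights <- function(grid) {
  G <- length(grid)
  if (G < 2L) stop("grid needs at least 2 points", call. = FALSE)
  d <- diff(grid)
  w <- numeric(G)
  w[1L] <- d[1L] / 2
  w[G] <- d[G - 1L] / 2
  if (G > 2L) w[2:(G - 1L)] <- (d[-(G - 1L)] + d[-1L]) / 2
  w
}

#' Trapezoidal integral of sampled values
#' @keywords internal
#' @noRd
trapz <- function(grid, values) sum(trapezoid_weights(grid) * values)

stop_input <- function(..., stage = NULL) {
  msg <- paste0(...)
  if (!is.null(stage)) msg <- paste0("[", stage, "] ", msg)
  stop(msg, call. = FALSE)
}

check_finite <- function(x, name, stage = NULL) {
  if (!all(is.finite(x))) {
    stop_input(name, " contains non-finite values", stage = stage)
  }
  invisible(x)
}
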