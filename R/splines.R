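#' B-spline specification with uniform interior knots
#'
#' Builds a clamped (open) uniform knot sequence on `domain`: the boundary
#' knots are repeated `order` times and `n_interior_knots` equally spaced
#' knots are placed strictly inside. The basis dimension is
#' `n_interior_knots + order` (i.e. `kn + h + 1` for splines of degree `h`).
#'
#' @param n_interior_knots Number of interior knots `kn >= 0`.
#' @param order Spline order `h + 1` (default 4, cubic splines).
#' @param domain Length-2 numeric, the interval carrying the index variable.
#' @return An object of class `spline_spec`.
#' @examples
#' spline_spec(3, 4) # cubic, 8 basis functions, knots at .25 .5 .75
#' @export
spline_spec <- function(n_interior_knots, order = 4L, domain = c(0, 1)) {
  kn <- as.integer(n_interior_knots)
  order <- as.integer(order)
  if (kn < 0L) stop_input("n_interior_knots must be >= 0")
  if (order < 1L) stop_input("order must be >= 1")
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) || diff(domain) <= 0) {
    stop_input("domain must be a finite increasing pair")
  }
  interior <- if (kn > 0L) {
    domain[1L] + diff(domain) * seq_len(kn) / (kn + 1)
  } else {
    numeric(0)
  }
  structure(
    list(
      n_interior_knots = kn,
      order = order,
      domain = domain,
      knot_vector = c(rep(domain[1L], order), interior, rep(domain[2L], order)),
      basis_dim = kn + order
    ),
    class = "spline_spec"
  )
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("<spline_spec> order ", x$order, " (degree ", x$order - 1L, "), ",
    x$n_interior_knots, " interior knots on [",
    format(x$domain[1L]), ", ", format(x$domain[2L]), "], dim ",
    x$basis_dim, "\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate the B-spline basis
#'
#' Returns the matrix of basis values \eqn{\pi(u)^T} row by row. Rows sum to
#' one (partition of unity) and all entries are non-negative; with clamped
#' knots the basis interpolates at the domain endpoints. Values outside the
#' domain raise an error — no extrapolation.
#'
#' @param u_values Numeric vector of evaluation points, inside the domain.
#' @param spec A [spline_spec()].
#' @return `length(u_values) x basis_dim` numeric matrix.
#' @export
basis_matrix <- function(u_values, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  u <- as.numeric(u_values)
  check_finite(u, "u_values")
  if (any(u < spec$domain[1L] | u > spec$domain[2L])) {
    bad <- which(u < spec$domain[1L] | u > spec$domain[2L])[1L]
    stop_input(
      "u value ", format(u[bad]), " outside the spline domain [",
      format(spec$domain[1L]), ", ", format(spec$domain[2L]), "]"
    )
  }
  ord <- order(u)
  B <- splines::splineDesign(spec$knot_vector, u[ord], ord = spec$order)
  B[order(ord), , drop = FALSE]
}

#' Default number of interior knots
#'
#' Encodes the knot-growth rate \eqn{k_n \asymp n^{1/(1+2r)}} for a
#' coefficient function with `r` continuous derivatives: the nearest integer
#' to `n^(1/(1+2r))` (ties rounded up), floored at 1 and capped at `n/10`.
#'
#' @param n Sample size.
#' @param r Assumed smoothness (default 2).
#' @return Integer number of interior knots.
#' @examples
#' default_kn(500) # 3
#' default_kn(2000) # 5
#' @export
default_kn <- function(n, r = 2) {
  if (n < 2) stop_input("n must be >= 2")
  kn <- floor(n^(1 / (1 + 2 * r)) + 0.5)
  as.integer(max(1, min(floor(n / 10), kn)))
}
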