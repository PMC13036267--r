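# Independent oracles used across tests. These deliberately re-derive
# quantities by the most literal route available (explicit risk-set
# enumeration, de Boor recursion, finite differences) and must stay
# independent of the package implementation they check.

# Brute-force negative log partial likelihood: explicit risk-set loops.
brute_neg_loglik <- function(delta, W, time, event) {
  lp <- drop(as.matrix(W) %*% delta)
  val <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      val <- val - (lp[i] - log(sum(exp(lp[risk]))))
    }
  }
  val
}

# Central finite differences of a scalar function.
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x))
    e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    ej <- numeric(d)
    ej[j] <- h
    for (k in j:d) {
      ek <- numeric(d)
      ek[k] <- h
      H[j, k] <- H[k, j] <-
        (f(x + ej + ek) - f(x + ej - ek) - f(x - ej + ek) + f(x - ej - ek)) /
          (4 * h^2)
    }
  }
  H
}

# de Boor recursion for a single B-spline basis function B_{j,ord}(x)
# over knot vector kv (1-based j). Independent of splines::splineDesign.
deboor_basis <- function(j, ord, kv, x) {
  if (ord == 1) {
    # half-open spans, except the last non-empty span which is closed
    last <- max(which(kv < kv[length(kv)]))
    hit <- (x >= kv[j] & x < kv[j + 1]) |
      (j == last & x == kv[length(kv)] & kv[j] < kv[j + 1])
    return(as.numeric(hit))
  }
  left <- 0
  if (kv[j + ord - 1] > kv[j]) {
    left <- (x - kv[j]) / (kv[j + ord - 1] - kv[j]) *
      deboor_basis(j, ord - 1, kv, x)
  }
  right <- 0
  if (kv[j + ord] > kv[j + 1]) {
    right <- (kv[j + ord] - x) / (kv[j + ord] - kv[j + 1]) *
      deboor_basis(j + 1, ord - 1, kv, x)
  }
  left + right
}

# Random small survival dataset with distinct times.
random_small_surv <- function(n, d, seed) {
  set.seed(seed)
  list(
    W = matrix(rnorm(n * d), n, d),
    time = sample(seq_len(n)) + runif(n, 0, 0.4),
    event = pmax(rbinom(n, 1, 0.7), c(1, rep(0, n - 1)))
  )
}

# Trapezoid quadrature (independent re-implementation for oracle use).
oracle_trapz <- function(grid, values) {
  sum(diff(grid) * (values[-1] + values[-length(values)]) / 2)
}

# Exact truncated Mercer covariance of the study design's covariate.
mercer_K <- function(grid, terms = 4) {
  K <- matrix(0, length(grid), length(grid))
  for (j in seq_len(terms)) {
    lam <- ((j - 0.5) * pi)^-2
    phi <- sqrt(2) * sin((j - 0.5) * pi * grid)
    K <- K + lam * tcrossprod(phi)
  }
  K
}
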