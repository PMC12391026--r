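# Internal helpers shared across modules.

# Deterministic sub-seed for a (seed, key) pair, so per-species random streams
# are independent of table order and of which other species are present.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# Multivariate-normal draws via symmetric eigendecomposition. Covariances that
# are PSD up to rounding are repaired by clipping eigenvalues in [-tol, 0] to
# zero; anything below -tol is treated as genuinely indefinite.
draw_mvnorm <- function(n, mean, sigma, tol = 1e-10) {
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  if (any(e$values < -tol)) {
    abort(sprintf(
      "covariance matrix is not positive semi-definite (min eigenvalue %.3g)",
      min(e$values)
    ))
  }
  vals <- pmax(e$values, 0)
  a <- e$vectors %*% diag(sqrt(vals), nrow = length(vals))
  z <- matrix(rnorm(n * length(vals)), nrow = n)
  sweep(z %*% t(a), 2, mean, "+")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
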