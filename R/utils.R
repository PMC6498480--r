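# Internal helpers shared across modules.

# Run `expr` under a local seed when one is supplied, otherwise use the
# current RNG stream. Keeps nested calls reproducible without touching the
# caller's RNG state.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# n draws from a mean-zero bivariate normal with covariance `cov` (2x2).
# Returns an n x 2 matrix. Handles rank-deficient (including zero)
# covariances via an eigen square root.
rmvn2 <- function(n, cov) {
  stopifnot(is.matrix(cov), all(dim(cov) == 2L))
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  rt <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  matrix(rnorm(2L * n), ncol = 2L) %*% rt
}

# Symmetric clamp of an estimated 2x2 covariance matrix onto the PSD cone:
# non-negative diagonals and |off-diagonal| <= sqrt(product of diagonals).
clamp_psd2 <- function(m) {
  d <- pmax(diag(m), 0)
  bound <- sqrt(d[1] * d[2])
  off <- min(max(m[1, 2], -bound), bound)
  matrix(c(d[1], off, off, d[2]), 2L, 2L)
}

is_psd2 <- function(m, tol = 1e-10) {
  is.matrix(m) && all(dim(m) == 2L) &&
    abs(m[1, 2] - m[2, 1]) <= tol * (1 + max(abs(m))) &&
    all(diag(m) >= -tol) &&
    (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) >= -tol * (1 + max(abs(m))^2)
}

# 2.5th/97.5th percentiles by linear interpolation between order statistics
# (quantile type 7), the package-wide central-range convention.
central_range_95 <- function(x) {
  unname(quantile(x, probs = c(0.025, 0.975), type = 7, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
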