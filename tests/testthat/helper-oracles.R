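# Shared oracles and fixture builders. Oracles are deliberately independent
# of the package's computation paths: the ARMA likelihood oracle builds the
# full autocovariance matrix from psi-weights, and regression oracles use
# stats::lm.

# ARMA autocovariance by psi-weight convolution (truncated MA(inf) form).
acvf_psi <- function(ar, ma, sigma2, nlag, J = 20000) {
  psi <- c(1, stats::ARMAtoMA(ar = ar, ma = ma, lag.max = J))
  vapply(0:nlag, function(h)
    sigma2 * sum(psi[1:(J + 1 - h)] * psi[(1 + h):(J + 1)]), numeric(1))
}

# Brute-force Gaussian log density of the observed coordinates of a
# stationary ARMA path (explicit Toeplitz covariance, Cholesky).
mvn_arma_loglik <- function(y, ar, ma, sigma2) {
  obs <- which(!is.na(y))
  n <- length(y)
  g <- acvf_psi(ar, ma, sigma2, n - 1)
  S <- stats::toeplitz(g[1:n])[obs, obs, drop = FALSE]
  L <- chol(S)
  z <- backsolve(L, y[obs], transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# random stationary coefficient draw through the package-independent route:
# partial autocorrelations in (-0.9, 0.9) mapped by the Durbin-Levinson
# recursion (re-implemented here so the test does not trust the package's)
dl_pacf_to_ar <- function(pacf) {
  a <- numeric(0)
  for (j in seq_along(pacf)) {
    if (j == 1) a <- pacf[1] else a <- c(a - pacf[j] * rev(a), pacf[j])
  }
  a
}
random_stationary_ar <- function(p) if (p == 0) numeric(0) else
  dl_pacf_to_ar(runif(p, -0.9, 0.9))
random_invertible_ma <- function(q) if (q == 0) numeric(0) else
  -dl_pacf_to_ar(runif(q, -0.9, 0.9))

# 15-minute grid helper
make_grid <- function(n, start = "2019-01-01") {
  seq(as.POSIXct(start, tz = "UTC"), by = 900, length.out = n)
}

make_aligned <- function(y, covs, site = "test") {
  aligned_dataset(make_grid(length(y)), y, covs, site = site)
}

# columns with exactly zero sample correlation (Gram-Schmidt on centered
# draws), unit variance
orthogonal_columns <- function(n, m) {
  X <- matrix(rnorm(n * m), n, m)
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))
  scale(Q, center = TRUE, scale = TRUE)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
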