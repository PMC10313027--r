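# ARIMA errors on additive-model residuals: exact Gaussian likelihood via a
# Kalman filter (C++ backend), stationarity/invertibility enforced through the
# partial-autocorrelation transform, innovation variance profiled.

#' ARIMA order specification
#'
#' @param p Autoregressive order (integer >= 0).
#' @param d Differencing order, 0 or 1.
#' @param q Moving-average order (integer >= 0).
#' @return An object of class `arma_spec`.
#' @export
arma_spec <- function(p, d = 0L, q = 0L) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  if (p < 0 || q < 0) stop("orders p and q must be non-negative")
  if (!d %in% c(0L, 1L)) stop("differencing order d must be 0 or 1")
  structure(list(p = p, d = d, q = q), class = "arma_spec")
}

#' @export
format.arma_spec <- function(x, ...) sprintf("ARIMA(%d,%d,%d)", x$p, x$d, x$q)

#' @export
print.arma_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# ---- stationarity / invertibility ------------------------------------------

# AR polynomial 1 - sum phi_j z^j must have all roots outside the unit circle.
is_stationary_ar <- function(phi, tol = 1e-8) {
  if (length(phi) == 0) return(TRUE)
  if (any(!is.finite(phi))) return(FALSE)
  all(Mod(polyroot(c(1, -phi))) > 1 + tol)
}

# MA polynomial 1 + sum theta_l z^l must have all roots outside the unit circle.
is_invertible_ma <- function(theta, tol = 1e-8) {
  if (length(theta) == 0) return(TRUE)
  if (any(!is.finite(theta))) return(FALSE)
  all(Mod(polyroot(c(1, theta))) > 1 + tol)
}

# ---- partial-autocorrelation parameter transform ---------------------------
# Durbin-Levinson maps between partial autocorrelations in (-1, 1) and the
# coefficients of a stationary AR polynomial; tanh maps the real line onto
# (-1, 1).  The same transform applied to MA coefficients enforces
# invertibility.  This is the classical re-parameterisation used by exact
# ARMA likelihood optimisers.

pacf_to_coef <- function(pacf) {
  k <- length(pacf)
  if (k == 0) return(numeric(0))
  a <- numeric(0)
  for (j in seq_len(k)) {
    if (j == 1) a <- pacf[1]
    else a <- c(a - pacf[j] * rev(a), pacf[j])
  }
  a
}

coef_to_pacf <- function(coef) {
  k <- length(coef)
  if (k == 0) return(numeric(0))
  pacf <- numeric(k)
  a <- coef
  for (j in rev(seq_len(k))) {
    pacf[j] <- a[j]
    if (j > 1) {
      denom <- 1 - a[j]^2
      if (denom <= 0) stop("coefficients outside the stationary region")
      a <- (a[-j] + a[j] * rev(a[-j])) / denom
    }
  }
  pacf
}

# Note the sign: 1 + sum theta_l z^l is invertible exactly when the AR
# polynomial with coefficients -theta is stationary.
trans_params <- function(u, p, q) {
  list(ar = pacf_to_coef(tanh(u[seq_len(p)])),
       ma = -pacf_to_coef(tanh(u[p + seq_len(q)])))
}

untrans_params <- function(ar, ma) {
  clamp <- function(z) pmin(pmax(z, -1 + 1e-10), 1 - 1e-10)
  c(atanh(clamp(coef_to_pacf(ar))), atanh(clamp(coef_to_pacf(-ma))))
}

# ---- state-space pieces ----------------------------------------------------

# Stationary state covariance at sigma2 = 1: solve P = T P T' + R R'
# (discrete Lyapunov) by the Kronecker identity; the state dimension is
# max(p, q + 1) so the solve is tiny.
arma_stationary_P0 <- function(phi, theta) {
  p <- length(phi); q <- length(theta)
  r <- max(p, q + 1L)
  Tm <- matrix(0, r, r)
  if (p > 0) Tm[seq_len(p), 1] <- phi
  if (r > 1) Tm[cbind(seq_len(r - 1), seq_len(r - 1) + 1)] <- 1
  R <- c(1, theta, rep(0, r - 1 - q))
  vecP <- solve(diag(r * r) - kronecker(Tm, Tm), as.vector(R %o% R))
  matrix(vecP, r, r)
}

# Difference within contiguous observed segments: a difference across a gap is
# undefined, so any pair with a missing member yields NA.
segment_diff <- function(y) {
  n <- length(y)
  if (n < 2) stop("series too short to difference")
  y[-1] - y[-n]
}

run_kf <- function(y, phi, theta, want_innov = FALSE) {
  .arma_kf_filter(as.numeric(y), as.numeric(phi), as.numeric(theta), want_innov)
}

# ---- log-likelihood --------------------------------------------------------

#' Exact Gaussian log-likelihood of an ARIMA model on a (gappy) series
#'
#' Evaluates the joint Gaussian log density of the observed values of a
#' zero-mean ARIMA(p,d,q) process by a state-space (Kalman filter) recursion.
#' Missing values are handled exactly: the filter predicts through gaps and
#' the result equals the marginal density over the observed coordinates.
#' With `d = 1` the series is differenced within contiguous observed segments
#' first (differences across gaps are treated as missing).
#'
#' @param y Numeric series, `NA` for missing.
#' @param spec An [arma_spec()].
#' @param ar,ma Coefficient vectors of lengths `spec$p`, `spec$q`.
#' @param sigma2 Innovation variance (> 0).
#' @return The log-likelihood (a scalar).
#' @export
arma_loglik <- function(y, spec, ar = numeric(0), ma = numeric(0), sigma2 = 1) {
  stopifnot(inherits(spec, "arma_spec"))
  if (length(ar) != spec$p || length(ma) != spec$q)
    stop("coefficient lengths must match the specified orders")
  if (!is_stationary_ar(ar)) stop("AR coefficients are non-stationary")
  if (!is_invertible_ma(ma)) stop("MA coefficients are non-invertible")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (length(y) <= spec$p + spec$q + spec$d)
    stop("series too short for the specified orders")
  if (spec$d == 1) y <- segment_diff(y)
  if (sum(!is.na(y)) < 1) stop("no observed values in the series")
  kf <- run_kf(y, ar, ma)
  if (!kf$ok) stop("Kalman filter failed (degenerate prediction variance)")
  -0.5 * (kf$nobs * log(2 * pi * sigma2) + kf$sumlogF + kf$ssq / sigma2)
}

# ---- fitting ---------------------------------------------------------------

# Hannan-Rissanen starting values: long-AR residuals stand in for the
# unobserved innovations, then a least-squares regression gives crude ARMA
# coefficients, pulled inside the stationary/invertible region if needed.
hannan_rissanen_start <- function(y, p, q) {
  yo <- y[!is.na(y)]
  n <- length(yo)
  if (p + q == 0) return(numeric(0))
  par <- tryCatch({
    m <- min(max(8L, 2L * (p + q)), max(1L, n %/% 5L))
    fit_ar <- stats::ar.yw(yo, aic = FALSE, order.max = m, demean = FALSE)
    eps <- as.numeric(fit_ar$resid)
    eps[is.na(eps)] <- 0
    k0 <- max(p, q)
    idx <- (k0 + 1):n
    X <- NULL
    for (j in seq_len(p)) X <- cbind(X, yo[idx - j])
    for (l in seq_len(q)) X <- cbind(X, eps[idx - l])
    cf <- as.numeric(qr.solve(qr(X, LAPACK = TRUE), yo[idx]))
    list(ar = cf[seq_len(p)], ma = cf[p + seq_len(q)])
  }, error = function(e) NULL)
  if (is.null(par)) par <- list(ar = rep(0, p), ma = rep(0, q))
  # shrink toward zero until valid
  shrink <- 1
  while ((!is_stationary_ar(par$ar * shrink) ||
          !is_invertible_ma(par$ma * shrink)) && shrink > 1e-4) {
    shrink <- shrink * 0.8
  }
  untrans_params(par$ar * shrink, par$ma * shrink)
}

#' Fit a zero-mean ARIMA model to a (gappy) residual series
#'
#' Maximum-likelihood estimation with the exact Gaussian likelihood of
#' [arma_loglik()].  Stationarity and invertibility are enforced through the
#' partial-autocorrelation transform; the innovation variance is profiled out.
#' The series mean is fixed at zero (additive-model residuals are centred by
#' construction), so no drift or intercept is estimated.
#'
#' @param y Numeric series, `NA` for missing.
#' @param spec An [arma_spec()].
#' @return An object of class `arma_fit` with elements `spec`, `ar`, `ma`,
#'   `sigma2`, `loglik`, `aic` (`-2 loglik + 2 (p + q + 1)`), `innovations`
#'   (standardised one-step prediction errors, `NA` at missing points, on the
#'   differenced scale when `d = 1`), `ss_innov`, `n_eff`, `converged` and
#'   `degenerate` flags.
#' @export
fit_arma <- function(y, spec) {
  stopifnot(inherits(spec, "arma_spec"))
  y_work <- if (spec$d == 1) segment_diff(y) else as.numeric(y)
  nobs <- sum(!is.na(y_work))
  if (nobs <= spec$p + spec$q + 1L)
    stop("series too short for the specified orders")

  degenerate <- FALSE
  v_obs <- var(y_work, na.rm = TRUE)
  if (!is.finite(v_obs) || v_obs < 1e-300) {
    # constant (typically all-zero) series: sigma2 collapses
    degenerate <- TRUE
  }

  p <- spec$p; q <- spec$q
  negll <- function(u) {
    par <- trans_params(u, p, q)
    kf <- run_kf(y_work, par$ar, par$ma)
    if (!kf$ok) return(1e10)
    s2 <- kf$ssq / kf$nobs
    if (!is.finite(s2) || s2 <= 0) return(1e10)
    0.5 * (kf$nobs * log(2 * pi) + kf$sumlogF + kf$nobs * log(s2) + kf$nobs)
  }

  # cheap conditional-sum-of-squares objective for warm starts
  negcss <- function(u) {
    par <- trans_params(u, p, q)
    cs <- .arma_css(y_work, par$ar, par$ma)
    if (cs$n_used < p + q + 2L) return(1e10)
    s2 <- cs$ssq / cs$n_used
    if (!is.finite(s2) || s2 <= 0) return(1e10)
    0.5 * cs$n_used * log(s2)
  }

  converged <- TRUE
  if (p + q == 0 || degenerate) {
    u_hat <- rep(0, p + q)
  } else {
    u0 <- hannan_rissanen_start(y_work, p, q)
    # CSS pre-optimisation, then exact-ML polish (the classic CSS-ML scheme)
    pre <- tryCatch(
      optim(u0, negcss, method = "BFGS",
            control = list(maxit = 60, reltol = 1e-9)),
      error = function(e) NULL)
    u1 <- if (!is.null(pre) && all(is.finite(pre$par))) pre$par else u0
    opt <- tryCatch(
      optim(u1, negll, method = "BFGS",
            control = list(maxit = 20, reltol = 1e-9)),
      error = function(e) NULL)
    # fall back to a derivative-free rescue if BFGS stumbles
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
      opt <- tryCatch({
        if (p + q == 1) {
          op <- optimize(function(u) negll(u), c(-5, 5), tol = 1e-9)
          list(par = op$minimum, value = op$objective, convergence = 0L)
        } else {
          optim(rep(0, p + q), negll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
        }
      }, error = function(e) NULL)
    }
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
      converged <- FALSE
      u_hat <- rep(0, p + q)
    } else {
      # convergence code 1 is the iteration cap: with a CSS warm start the
      # fit is near the optimum, so it stays usable (a hard failure does not)
      u_hat <- opt$par
    }
  }

  par <- trans_params(u_hat, p, q)
  kf <- run_kf(y_work, par$ar, par$ma, want_innov = TRUE)
  sigma2 <- kf$ssq / kf$nobs
  if (!is.finite(sigma2) || sigma2 < 1e-300) {
    degenerate <- TRUE
    sigma2 <- max(sigma2, .Machine$double.xmin)
  }
  loglik <- -0.5 * (kf$nobs * log(2 * pi) + kf$sumlogF +
                      kf$nobs * log(sigma2) + kf$nobs)
  innov <- kf$v / sqrt(kf$F)  # standardised to common variance sigma2

  # overparameterization diagnostics, both standard practice for ARMA fits:
  # (i) a root of the AR or MA polynomial within 1% of the unit circle
  #     signals a spurious narrow-band (spectral-line) component — the
  #     rejection rule of forecast::auto.arima;
  # (ii) an AR root nearly equal to an MA root is a near-common factor, the
  #     classical Box-Jenkins symptom of parameter redundancy (the pair
  #     cancels, leaving an unidentifiable ridge in the likelihood).
  ar_roots <- if (p > 0) polyroot(c(1, -par$ar)) else complex(0)
  ma_roots <- if (q > 0) polyroot(c(1, par$ma)) else complex(0)
  minroot <- min(2, Mod(ar_roots), Mod(ma_roots))
  redundancy_gap <- if (p > 0 && q > 0)
    min(Mod(outer(ar_roots, ma_roots, `-`))) else Inf

  structure(list(
    spec = spec, ar = par$ar, ma = par$ma, sigma2 = sigma2,
    loglik = loglik, aic = -2 * loglik + 2 * (p + q + 1),
    innovations = innov, ss_innov = kf$ssq, n_eff = kf$nobs,
    converged = converged, degenerate = degenerate,
    min_root = minroot, boundary = minroot < 1.01,
    redundant = redundancy_gap < 0.05
  ), class = "arma_fit")
}

#' @export
print.arma_fit <- function(x, ...) {
  cat(format(x$spec), " fitted by exact ML (n_eff = ", x$n_eff, ")\n", sep = "")
  if (x$spec$p > 0) cat("  ar:", signif(x$ar, 4), "\n")
  if (x$spec$q > 0) cat("  ma:", signif(x$ma, 4), "\n")
  cat("  sigma2 =", signif(x$sigma2, 5), " loglik =", signif(x$loglik, 6),
      " AIC =", signif(x$aic, 6), "\n")
  if (x$degenerate) cat("  [degenerate: innovation variance ~ 0]\n")
  if (!x$converged) cat("  [optimizer did not converge]\n")
  invisible(x)
}

#' Select an ARIMA order for a residual series by AIC grid search
#'
#' Fits every ARIMA(p,d,q) on the grid `p = 0..p_max`, `d = 0..d_max`,
#' `q = 0..q_max` with [fit_arma()] and returns the converged fit with
#' minimal AIC.  Ties are broken by smaller `p + q`, then smaller `q`.
#' Defaults cover AR/MA orders up to (5, 4) with at most one difference.
#'
#' @param y Numeric series, `NA` for missing.
#' @param p_max,d_max,q_max Grid bounds (defaults 5, 1, 4).
#' @return The selected `arma_fit`, with a `selection` attribute holding the
#'   per-cell AIC table.
#' @export
select_arma_order <- function(y, p_max = 5L, d_max = 1L, q_max = 4L) {
  stopifnot(p_max >= 0, d_max >= 0, d_max <= 1, q_max >= 0)
  grid <- expand.grid(p = 0:p_max, d = 0:d_max, q = 0:q_max)
  fits <- vector("list", nrow(grid))
  aics <- rep(NA_real_, nrow(grid))
  notes <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(
      fit_arma(y, arma_spec(grid$p[i], grid$d[i], grid$q[i])),
      error = function(e) e)
    if (inherits(f, "error")) { notes[i] <- conditionMessage(f); next }
    if (!f$converged) { notes[i] <- "non-convergent"; next }
    if (f$boundary && (grid$p[i] + grid$q[i]) > 0) {
      notes[i] <- "root within 1% of unit circle"; next
    }
    if (f$redundant) { notes[i] <- "near-common AR/MA factor"; next }
    fits[[i]] <- f
    aics[i] <- f$aic
    notes[i] <- "ok"
  }
  if (all(is.na(aics)))
    stop("no ARIMA fit converged on the search grid; diagnostics: ",
         paste(unique(notes), collapse = "; "))
  ord <- order(aics, grid$p + grid$q, grid$q)
  best <- fits[[ord[1]]]
  attr(best, "selection") <- cbind(grid, aic = aics, note = notes)
  best
}
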