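test_that("smooth basis has the contracted structure", {
  set.seed(1)
  x <- runif(100, 0, 10)
  b <- build_smooth_basis(x, max_df = 6)
  expect_equal(ncol(b$X), 6)
  expect_equal(colMeans(b$X), rep(0, 6), tolerance = 1e-10)
  expect_equal(b$S, t(b$S), tolerance = 1e-12)
  ev <- eigen(b$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(abs(ev))))  # PSD
  # penalty null space contains the linear trend: a linear function of x
  # lies in the basis span and is unpenalized
  lin_fit <- lm.fit(cbind(1, b$X), x)
  expect_lt(max(abs(lin_fit$residuals)), 1e-8 * diff(range(x)))
  beta_lin <- lin_fit$coefficients[-1]
  expect_lt(drop(t(beta_lin) %*% b$S %*% beta_lin),
            1e-8 * sum(beta_lin^2) * max(abs(ev)))

  expect_error(build_smooth_basis(rep(1, 50)), "degenerate")
  expect_error(build_smooth_basis(rep(1:4, 20)), "degenerate")
})

test_that("penalized fit is exact on linear truth and recovers a sine", {
  set.seed(2)
  n <- 1500
  x1 <- runif(n, -2, 2); x2 <- runif(n, -2, 2)
  d <- make_aligned(3 + 1.5 * x1, data.frame(x1 = x1, x2 = x2))
  f <- fit_penalized_gam(d, "x1")
  expect_equal(f$deviance_explained, 100, tolerance = 1e-8)
  pe <- evaluate_partial_effects(f, 50)
  line <- 1.5 * (pe$value - mean(x1))
  expect_lt(max(abs(pe$effect - line)), 1e-6 * diff(range(d$response)))

  y2 <- 1 + sin(pi * x1 / 2) + rnorm(n, 0, 0.1)
  d2 <- make_aligned(y2, data.frame(x1 = x1, x2 = x2))
  f2 <- fit_penalized_gam(d2, "x1")
  pe2 <- evaluate_partial_effects(f2, 100)
  truth <- sin(pi * pe2$value / 2) - mean(sin(pi * x1 / 2))
  expect_lt(sqrt(mean((pe2$effect - truth)^2)), 0.05)

  f0 <- fit_penalized_gam(d2, character(0), candidates = "x1")
  expect_equal(f0$deviance_explained, 0)
  expect_equal(f0$fitted, rep(mean(y2), n))
})

test_that("edf accounting matches the influence-matrix trace", {
  set.seed(3)
  n <- 300
  x1 <- runif(n); x2 <- runif(n)
  y <- sin(2 * x1) + 0.5 * x2^2 + rnorm(n, 0, 0.2)
  d <- make_aligned(y, data.frame(x1 = x1, x2 = x2))
  f <- fit_penalized_gam(d, c("x1", "x2"))
  ws <- f$workspace
  lam <- c(x1 = f$terms$x1$lambda, x2 = f$terms$x2$lambda)
  X <- ws$X
  M <- ws$XtX
  M[2:7, 2:7] <- M[2:7, 2:7] + lam["x1"] * f$terms$x1$basis$S
  M[8:13, 8:13] <- M[8:13, 8:13] + lam["x2"] * f$terms$x2$basis$S
  H <- X %*% solve(M, t(X))
  expect_equal(f$edf_total, sum(diag(H)), tolerance = 1e-6)
})

test_that("large-lambda limit reproduces OLS and rss is monotone in lambda", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 250
    x1 <- runif(n); x2 <- rnorm(n)
    y <- 1 + 2 * x1 - x2 + rnorm(n, 0, 0.5)
    d <- make_aligned(y, data.frame(x1 = x1, x2 = x2))
    f <- fit_penalized_gam(d, c("x1", "x2"),
                           lambda = c(x1 = 1e12, x2 = 1e12))
    ols <- lm(y ~ x1 + x2)
    co <- coef(lm(f$fitted ~ x1 + x2))
    expect_equal(unname(co), unname(coef(ols)), tolerance = 1e-6)
  }

  # rss non-increasing as lambda decreases
  set.seed(5)
  n <- 400
  x <- runif(n)
  y <- sin(6 * x) + rnorm(n, 0, 0.3)
  d <- make_aligned(y, data.frame(x = x))
  rss_at <- function(l) fit_penalized_gam(d, "x", lambda = c(x = l))$rss
  ls <- 10^seq(4, -4, by = -2)
  rs <- vapply(ls, rss_at, numeric(1))
  expect_true(all(diff(rs) <= 1e-8 * rs[1]))
})

test_that("fits are invariant to affine covariate rescaling and to adding terms", {
  set.seed(6)
  n <- 600
  x1 <- runif(n, 0, 1); x2 <- rnorm(n)
  y <- sin(3 * x1) + rnorm(n, 0, 0.2)
  d <- make_aligned(y, data.frame(x1 = x1, x2 = x2))
  f <- fit_penalized_gam(d, "x1")
  d2 <- make_aligned(y, data.frame(x1 = 100 * x1 - 37, x2 = x2))
  f2 <- fit_penalized_gam(d2, "x1")
  expect_equal(f2$fitted, f$fitted, tolerance = 1e-2)
  expect_equal(f2$deviance_explained, f$deviance_explained, tolerance = 0.1)

  fb <- fit_penalized_gam(d, c("x1", "x2"), candidates = c("x1", "x2"))
  fa <- fit_penalized_gam(d, "x1", candidates = c("x1", "x2"))
  expect_gte(fb$deviance_explained, fa$deviance_explained - 1e-6)
})

test_that("stepwise selection keeps strong effects and reports its trace", {
  set.seed(7)
  n <- 1200
  x1 <- runif(n, -2, 2); x2 <- rnorm(n)
  y <- 2 + tanh(1.5 * x1) + rnorm(n, 0, 0.3)
  d <- make_aligned(y, data.frame(x1 = x1, x2 = x2))
  s <- stepwise_select_gam(d, c("x1", "x2"))
  expect_true("x1" %in% names(s$terms))
  f0 <- fit_penalized_gam(d, character(0), candidates = c("x1", "x2"))
  expect_lt(s$aic, f0$aic)
  tr <- attr(s, "trace")
  expect_true(is.data.frame(tr) && nrow(tr) >= 1)
  expect_true(all(diff(tr$aic) < 0))  # every accepted move lowers AIC
})

test_that("partial effect tables honour grid arguments and centering", {
  set.seed(8)
  n <- 500
  x <- runif(n, 2, 9)
  y <- 0.8 * x + rnorm(n, 0, 0.2)
  d <- make_aligned(y, data.frame(x = x))
  f <- fit_penalized_gam(d, "x")
  pe <- evaluate_partial_effects(f, 2)
  expect_equal(nrow(pe), 2)
  expect_equal(pe$value, range(x))
  # centering: effect at the covariate mean is near zero
  pe2 <- evaluate_partial_effects(f, 201)
  at_mean <- pe2$effect[which.min(abs(pe2$value - mean(x)))]
  expect_lt(abs(at_mean), 0.05 * diff(range(f$fitted)))
  expect_error(evaluate_partial_effects(f, 1), "grid_points")
})

test_that("collinear smooth designs raise a helpful error", {
  set.seed(9)
  n <- 300
  x <- runif(n)
  d <- make_aligned(rnorm(n), data.frame(a = x, b = x))
  expect_error(fit_penalized_gam(d, c("a", "b")), "collinear|singular")
})
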