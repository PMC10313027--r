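test_that("covariate simulation honours degenerate and sinusoid recipes", {
  flat <- list(x = list(mean = 5, diel_amp = 0, diel_phase = 0,
                        seasonal_amp = 0, seasonal_phase = 0,
                        ar1 = 0, noise_sd = 0))
  sp <- truth_spec(n = 500, covariates = flat, smooths = list(), seed = 1)
  set.seed(1)
  cv <- simulate_covariates(sp)
  expect_equal(cv$x, rep(5, 500))

  diel <- list(x = list(mean = 0, diel_amp = 3, diel_phase = 0.7,
                        seasonal_amp = 0, seasonal_phase = 0,
                        ar1 = 0, noise_sd = 0))
  sp2 <- truth_spec(n = 96 * 3, covariates = diel, smooths = list(), seed = 1)
  set.seed(1)
  cv2 <- simulate_covariates(sp2)
  day1 <- cv2$x[1:96]
  expect_equal(max(day1) - min(day1), 6, tolerance = 0.01)

  # event count lies in the Poisson 99% interval of its mean (rate 1/10
  # days over 100 days -> mean 10)
  ev <- list(x = list(mean = 0, diel_amp = 0, diel_phase = 0,
                      seasonal_amp = 0, seasonal_phase = 0,
                      ar1 = 0, noise_sd = 0,
                      events = list(rate_per_day = 0.1, height = 5,
                                    decay_days = 0.05)))
  sp3 <- truth_spec(n = 9600, covariates = ev, smooths = list(), seed = 42)
  set.seed(42)
  cv3 <- simulate_covariates(sp3)
  # pulses are near-instant spikes; count upward jumps larger than half the
  # pulse height
  jumps <- sum(diff(cv3$x) > 2.5)
  expect_gte(jumps, qpois(0.005, 10))
  expect_lte(jumps, qpois(0.995, 10))

  bad <- ev
  bad$x$events$decay_days <- -1
  expect_error(truth_spec(n = 100, covariates = bad, smooths = list(),
                          seed = 1), "decay")
})

test_that("ARMA error paths match theoretical moments", {
  sp_wn <- truth_spec(arma = list(ar = numeric(0), ma = numeric(0),
                                  sigma = 2), seed = 1)
  set.seed(31)
  e <- simulate_arma_errors(sp_wn, 1e5)
  expect_equal(var(e), 4, tolerance = 0.05 * 4)

  sp_ar <- truth_spec(arma = list(ar = 0.8, ma = numeric(0), sigma = 1),
                      seed = 1)
  set.seed(32)
  e2 <- simulate_arma_errors(sp_ar, 1e5)
  expect_equal(unname(acf(e2, plot = FALSE, lag.max = 1)$acf[2]), 0.8,
               tolerance = 0.02)

  sp_ma <- truth_spec(arma = list(ar = numeric(0), ma = 0.6, sigma = 1),
                      seed = 1)
  set.seed(33)
  e3 <- simulate_arma_errors(sp_ma, 1e5)
  a <- acf(e3, plot = FALSE, lag.max = 2)$acf
  expect_equal(unname(a[2]), 0.6 / 1.36, tolerance = 0.02)
  expect_equal(unname(a[3]), 0, tolerance = 0.02)

  expect_error(truth_spec(arma = list(ar = 1.05, ma = numeric(0),
                                      sigma = 1), seed = 1),
               "non-stationary")
})

test_that("simulate_dataset satisfies the forward-model identity and determinism", {
  sp <- truth_spec(n = 3000, seed = 99)
  sd1 <- simulate_dataset(sp)
  sd2 <- simulate_dataset(sp)
  expect_identical(sd1$data$response, sd2$data$response)
  expect_identical(sd1$truth, sd2$truth)

  contrib <- rowSums(sd1$truth[, names(sp$smooths), drop = FALSE])
  expect_equal(sd1$truth$response_clean,
               sp$beta0 + contrib + sd1$truth$eta, tolerance = 1e-12)

  # gaps and anomalies injected at roughly the requested rates
  expect_equal(mean(sd1$truth$gap), sp$gap_frac, tolerance = 0.05)
  expect_equal(sum(sd1$truth$anomaly), round(sp$anomaly_frac * sp$n))

  # constant world: all-zero smooths, zero noise
  sp0 <- truth_spec(n = 300, smooths = list(),
                    arma = list(ar = numeric(0), ma = numeric(0),
                                sigma = 1e-12),
                    gap_frac = 0, anomaly_frac = 0, seed = 7)
  sd0 <- simulate_dataset(sp0)
  expect_equal(sd0$data$response, rep(sp0$beta0, 300), tolerance = 1e-6)
})

test_that("scenario presets order their nitrate levels as designed", {
  meds <- vapply(c("low", "medium", "high"), function(nm) {
    s <- simulate_dataset(scenario_spec(nm, seed = 5, n = 2000))
    median(s$data$response, na.rm = TRUE)
  }, numeric(1))
  expect_true(meds["low"] < meds["medium"] && meds["medium"] < meds["high"])
  # design centres: about 5.5, 28.4, 192 umol/L
  expect_equal(unname(meds), c(5.5, 28.4, 192), tolerance = 0.15)
})

test_that("generated records round-trip through the alignment pipeline", {
  sp <- truth_spec(n = 1500, seed = 13)
  sdat <- simulate_dataset(sp)
  al <- align_to_response_grid(sdat$records, tolerance = 60,
                               site = sp$site)
  # same grid span and response wherever the clean view is observed
  expect_equal(length(al$grid), length(sdat$data$grid))
  obs <- !is.na(sdat$data$response)
  expect_equal(al$response[obs], sdat$data$response[obs], tolerance = 1e-12)
  # anomalous rows were excluded by the aligner too
  expect_true(all(is.na(al$response[sdat$truth$anomaly])))
  for (nm in names(sdat$data$covariates))
    expect_equal(al$covariates[[nm]], sdat$data$covariates[[nm]],
                 tolerance = 1e-12)
})
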