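test_that("read_sensor_table parses canonical and NEON-style layouts identically", {
  canon <- write_temp_csv(c(
    "timestamp,value,qc_flag",
    "2019-01-01T00:00:00Z,12.5,0",
    "2019-01-01T00:15:00Z,12.9,0",
    "2019-01-01T00:30:00Z,13.1,1"))
  rec <- read_sensor_table(canon, list(timestamp = "timestamp",
                                       value = "value", flag = "qc_flag",
                                       variable = "nitrate"))
  expect_s3_class(rec, "sensor_records")
  expect_equal(nrow(rec), 3)
  expect_true(!is.unsorted(rec$timestamp))
  expect_equal(rec$value, c(12.5, 12.9, 13.1))
  expect_equal(rec$qc_flag, c(FALSE, FALSE, TRUE))
  expect_equal(attr(rec, "rejected"), 0)

  neon <- write_temp_csv(c(
    "startDateTime,surfWaterNitrateMean,finalQF",
    "2019-01-01T00:00:00Z,12.5,0",
    "2019-01-01T00:15:00Z,12.9,0",
    "2019-01-01T00:30:00Z,13.1,1"))
  rec2 <- read_sensor_table(neon, list(timestamp = "startDateTime",
                                       value = "surfWaterNitrateMean",
                                       flag = "finalQF",
                                       variable = "nitrate"))
  expect_equal(rec2$timestamp, rec$timestamp)
  expect_equal(rec2$value, rec$value)
  expect_equal(rec2$qc_flag, rec$qc_flag)
})

test_that("read_sensor_table rejects malformed rows and bad inputs", {
  f <- write_temp_csv(c(
    "timestamp,value",
    "2019-01-01T00:00:00Z,1.0",
    "2019-01-01T00:15:00Z,not-a-number",
    "2019-01-01T00:30:00Z,3.0"))
  dia <- list(timestamp = "timestamp", value = "value", variable = "nitrate")
  expect_message(rec <- read_sensor_table(f, dia), "rejected 1")
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "rejected"), 1)

  f2 <- write_temp_csv(c("timestamp,value", "2019-01-01T00:00:00Z,1.0"))
  expect_error(read_sensor_table(f2, list(timestamp = "when", value = "value",
                                          variable = "nitrate")),
               "missing required column")
  f3 <- write_temp_csv("timestamp,value")
  expect_error(read_sensor_table(f3, dia), "empty")
  expect_error(read_sensor_table(f, list(value = "value")), "missing required key")
})

test_that("alignment matches nearest-in-tolerance and never invents data", {
  g <- make_grid(8)
  nit <- data.frame(timestamp = g, variable = "nitrate",
                    value = 1:8, qc_flag = FALSE)
  # covariate measured exactly at each nitrate timestamp
  cov_exact <- data.frame(timestamp = g, variable = "temperature",
                          value = 21:28, qc_flag = FALSE)
  al <- align_to_response_grid(bind_sensor_records(nit, cov_exact))
  expect_equal(al$response, 1:8)
  expect_equal(al$covariates$temperature, 21:28)

  # 1-minute cadence covariate, 60 s tolerance: the coincident minute wins
  t1min <- seq(g[1], g[8], by = 60)
  cov1m <- data.frame(timestamp = t1min, variable = "dissolved_oxygen",
                      value = as.numeric(t1min) / 60, qc_flag = FALSE)
  al2 <- align_to_response_grid(bind_sensor_records(nit, cov1m),
                                tolerance = 60)
  expect_equal(al2$covariates$dissolved_oxygen, as.numeric(g) / 60)

  # covariate only 10 minutes off, 60 s tolerance: missing
  cov_off <- data.frame(timestamp = g[3] + 600, variable = "turbidity",
                        value = 99, qc_flag = FALSE)
  al3 <- align_to_response_grid(bind_sensor_records(nit, cov_off),
                                tolerance = 60)
  expect_true(all(is.na(al3$covariates$turbidity)))

  # anomalous records are excluded before matching
  nit_flag <- nit; nit_flag$qc_flag[4] <- TRUE
  al4 <- align_to_response_grid(bind_sensor_records(nit_flag, cov_exact))
  expect_true(is.na(al4$response[4]))
  expect_equal(al4$qc$anomalous_removed, 1)

  # never invents data: every non-missing covariate cell is an input value
  vals <- al2$covariates$dissolved_oxygen
  expect_true(all(vals[!is.na(vals)] %in% cov1m$value))

  expect_error(align_to_response_grid(bind_sensor_records(cov_exact)),
               "no .*nitrate")
})

test_that("turbidity transform is exact, validated, and single-shot", {
  y <- rnorm(20) + 10
  d <- make_aligned(y, data.frame(turbidity = c(0, exp(1) - 1, 95.45,
                                                rep(1, 17))))
  d2 <- transform_covariates(d)
  expect_equal(d2$covariates$turbidity[1], 0)
  expect_equal(d2$covariates$turbidity[2], 1)
  expect_equal(d2$covariates$turbidity[3], log(96.45), tolerance = 1e-12)
  expect_error(transform_covariates(d2), "already been applied")

  dneg <- make_aligned(y, data.frame(turbidity = c(-1, rep(1, 19))))
  expect_error(transform_covariates(dneg), "negative turbidity")
})

test_that("vif_screen matches the least-squares oracle and handles collinearity", {
  set.seed(11)
  n <- 200
  X <- orthogonal_columns(n, 3)
  d <- make_aligned(rnorm(n), as.data.frame(X))
  vr <- vif_screen(d, c("V1", "V2", "V3"))
  expect_equal(unname(vr$vif), rep(1, 3), tolerance = 1e-10)
  expect_length(vr$dropped, 0)

  # two covariates with sample correlation exactly 0.9, a third orthogonal
  x1 <- X[, 1]
  e <- X[, 2]
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e
  d2 <- make_aligned(rnorm(n), data.frame(a = x1, b = x2, c = X[, 3]))
  vr2 <- vif_screen(d2, c("a", "b", "c"))
  expect_equal(unname(vr2$vif[c("a", "b")]), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)
  expect_length(vr2$dropped, 0)  # 5.26 < 6

  # oracle comparison on a random correlated design
  set.seed(12)
  Z <- matrix(rnorm(n * 4), n, 4)
  Z[, 2] <- Z[, 2] + 0.7 * Z[, 1]
  dz <- make_aligned(rnorm(n), as.data.frame(Z))
  vrz <- vif_screen(dz, paste0("V", 1:4), threshold = 1e6)
  for (j in 1:4) {
    r2 <- summary(lm(Z[, j] ~ Z[, -j]))$r.squared
    expect_equal(unname(vrz$vif[paste0("V", j)]), 1 / (1 - r2),
                 tolerance = 1e-8)
  }

  # exact linear combination diverges and is dropped first
  Z2 <- data.frame(a = Z[, 1], b = Z[, 2], lc = Z[, 1] + Z[, 2])
  dlc <- make_aligned(rnorm(n), Z2)
  vrl <- vif_screen(dlc, names(Z2))
  expect_equal(vrl$dropped[1], "lc")

  # permutation and affine-scale invariance
  vp <- vif_screen(dz, c("V3", "V1", "V4", "V2"), threshold = 1e6)
  expect_equal(sort(vp$vif), sort(vrz$vif), tolerance = 1e-8)
  Zs <- as.data.frame(sweep(Z, 2, c(10, 0.01, 3, 100), `*`))
  Zs <- as.data.frame(lapply(Zs, function(v) v + 5))
  ds <- make_aligned(rnorm(n), Zs)
  vs <- vif_screen(ds, paste0("V", 1:4), threshold = 1e6)
  expect_equal(unname(vs$vif), unname(vrz$vif), tolerance = 1e-6)

  # identifiability guard
  dshort <- make_aligned(c(rnorm(3), rep(NA, n - 3)), as.data.frame(Z))
  expect_error(vif_screen(dshort, paste0("V", 1:4)), "too few complete rows")
})

test_that("summarise_variables reports standard quantiles and handles edge cases", {
  d <- make_aligned(c(1, 2, 3, 4, 5),
                    data.frame(const = rep(7, 5), hole = rep(NA_real_, 5)))
  s <- summarise_variables(d)
  resp <- s[s$variable == "response", ]
  expect_equal(resp[, c("median", "q1", "q3")],
               data.frame(median = 3, q1 = 2, q3 = 4),
               ignore_attr = TRUE)
  cst <- s[s$variable == "const", ]
  expect_equal(cst$q3 - cst$q1, 0)
  expect_equal(cst$mean, 7)
  expect_equal(cst$median, 7)
  hole <- s[s$variable == "hole", ]
  expect_equal(hole$n, 0)
  expect_true(is.na(hole$mean))

  # right-skew signature: lognormal mean exceeds its third quartile
  set.seed(5)
  v <- rlnorm(10000, meanlog = 1, sdlog = 2)
  dv <- make_aligned(rnorm(10000), data.frame(turb_like = v))
  sv <- summarise_variables(dv)
  row <- sv[sv$variable == "turb_like", ]
  expect_gt(row$mean, row$q3)

  # turbidity summarised on the raw FNU scale after the log transform
  dt <- make_aligned(rnorm(20), data.frame(turbidity = rexp(20, 0.1)))
  raw_mean <- mean(dt$covariates$turbidity)
  st <- summarise_variables(transform_covariates(dt))
  expect_equal(st[st$variable == "turbidity", "mean"], raw_mean,
               tolerance = 1e-10)
})

test_that("aligned datasets round-trip through CSV with metadata", {
  set.seed(3)
  d <- make_aligned(rnorm(30), data.frame(turbidity = rexp(30)))
  d <- transform_covariates(d)
  f <- tempfile(fileext = ".csv")
  write_aligned_dataset(d, f)
  d2 <- read_aligned_dataset(f)
  expect_equal(d2$response, d$response, tolerance = 1e-12)
  expect_equal(d2$covariates$turbidity, d$covariates$turbidity,
               tolerance = 1e-12)
  expect_equal(d2$transforms, "log1p_turbidity")
})
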