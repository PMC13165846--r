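test_that("zero-lag Butterworth has unit DC gain and the analytic rolloff", {
  expect_equal(zero_lag_butterworth(rep(2.5, 500), fs = 100), rep(2.5, 500),
               tolerance = 1e-6)

  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  fit_amp <- function(y, f) {
    X <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    co <- stats::coef(stats::lm(y ~ X - 1))
    sqrt(sum(co^2))
  }
  low <- sin(2 * pi * 1 * tt)
  out <- zero_lag_butterworth(low, fs)
  expect_equal(fit_amp(out, 1), 1, tolerance = 0.01)
  # zero net phase: cross-correlation peak at zero lag
  cc <- stats::ccf(out, low, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  hi <- sin(2 * pi * 40 * tt)
  out_hi <- zero_lag_butterworth(hi, fs)
  analytic <- 1 / (1 + (40 / 6)^(2 * 4))   # squared 4th-order response
  expect_lt(fit_amp(out_hi, 40), analytic + 1e-6)

  expect_error(zero_lag_butterworth(1:5, fs = 100),
               class = "gait_error_insufficient_data")
  expect_error(zero_lag_butterworth(low, fs = 10, fc = 6),
               class = "gait_error_invalid_argument")
})

test_that("cross-correlation alignment recovers injected lags exactly", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 0.7 * tt) + 0.4 * sin(2 * pi * 1.9 * tt + 1)
  lag <- 37 / fs
  test_series <- tibble::tibble(time = tt + lag, value = x)
  ref_series <- tibble::tibble(time = tt, value = x)
  pair <- align_by_xcorr(test_series, ref_series, fs_out = fs)
  # the test stream carries the same values later in time: it trails the
  # reference by `lag`
  expect_equal(pair$lag, -lag, tolerance = 1e-9)
  expect_lt(max(abs(pair$test - pair$reference)), 1e-6)

  # linear interpolation is exact on lines: a 200 Hz ramp (with one bump to
  # pin the correlation) resampled to 100 Hz reproduces the line exactly
  t200 <- seq(0, 20, by = 1 / 200)
  bump <- exp(-((t200 - 10) / 0.1)^2)
  ramp_t <- tibble::tibble(time = t200, value = 3 * t200 - 1 + bump)
  ramp_r <- tibble::tibble(time = tt, value = 3 * tt - 1 +
                             exp(-((tt - 10) / 0.1)^2))
  pair <- align_by_xcorr(ramp_t, ramp_r)
  away <- abs(pair$time - 10) > 1
  expect_equal(pair$test[away], (3 * pair$time - 1)[away], tolerance = 1e-9)

  # interpolation error on a smooth sinusoid obeys the h^2 max|f''| / 8 bound
  f <- 1.3
  sin200 <- tibble::tibble(time = seq(0, 20, by = 1 / 200),
                           value = sin(2 * pi * f * seq(0, 20, by = 1 / 200)))
  pair <- align_by_xcorr(sin200, sin200, fs_out = 100)
  bound <- (1 / 200)^2 * (2 * pi * f)^2 / 8
  expect_lt(max(abs(pair$test - sin(2 * pi * f * pair$time))), bound + 1e-12)

  expect_error(align_by_xcorr(ref_series[1:50, ], ref_series),
               class = "gait_error_insufficient_data")
  set.seed(2)
  noise_a <- tibble::tibble(time = tt, value = stats::rnorm(length(tt)))
  noise_b <- tibble::tibble(time = tt, value = stats::rnorm(length(tt)))
  expect_error(align_by_xcorr(noise_a, noise_b),
               class = "gait_error_alignment_failure")
})

test_that("agreement metrics match their closed forms", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 0.3)
  rep1 <- agreement_metrics(x, x)
  expect_equal(rep1$rmse, 0)
  expect_equal(rep1$pearson_r, 1)
  expect_equal(rep1$icc, 1)
  expect_equal(rep1$bias, 0)
  expect_equal(c(rep1$loa_low, rep1$loa_high), c(0, 0))

  rep2 <- agreement_metrics(x + 2, x)
  expect_equal(rep2$bias, 2)
  expect_equal(rep2$rmse, 2)
  expect_equal(c(rep2$loa_low, rep2$loa_high), c(2, 2))
  expect_equal(rep2$pearson_r, 1)

  # RMSE^2 = bias^2 + population variance of the differences
  set.seed(12)
  a <- stats::rnorm(500); b <- a + stats::rnorm(500, 0.3, 0.5)
  r <- agreement_metrics(a, b)
  d <- a - b
  expect_equal(r$rmse^2, r$bias^2 + mean((d - mean(d))^2),
               tolerance = 1e-12)

  expect_warning(agreement_metrics(rep(1, 5), 1:5),
                 class = "gait_warning_undefined_statistic")
  expect_error(agreement_metrics(1:2, 1:2),
               class = "gait_error_invalid_argument")
})

test_that("published-style relative RMSE arithmetic reproduces the table", {
  ref <- spatiotemporal_reference()
  expect_equal(round(relative_rmse(ref$rmse, ref$omc_mean), 1),
               ref$published_rel_rmse_pct)
  # the specific gait-cycle pair: 0.167 s RMSE on a 1.05 s mean
  expect_equal(round(relative_rmse(0.167, 1.05), 1), 15.9)
})

test_that("ICC(2,1) agrees with an ANOVA-based oracle", {
  set.seed(33)
  n <- 40
  subj <- stats::rnorm(n, 20, 5)
  test <- subj + stats::rnorm(n, 0.5, 1.2)
  ref <- subj + stats::rnorm(n, 0, 1.0)
  icc <- icc_2_1(test, ref)

  df <- data.frame(
    y = c(test, ref),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("t", "r"), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  expect_equal(icc, oracle, tolerance = 1e-12)
  expect_gt(icc, 0.8)
})

test_that("limits of agreement contain ~95% of Gaussian differences", {
  set.seed(77)
  n <- 10000
  ref <- stats::rnorm(n, 50, 8)
  test <- ref + stats::rnorm(n, 0.4, 1.5)
  r <- agreement_metrics(test, ref)
  d <- test - ref
  inside <- mean(d >= r$loa_low & d <= r$loa_high)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.96)
})
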