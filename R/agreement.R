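#' Method-comparison pipeline against a reference system
#'
#' Reproduces the comparison protocol used to validate IMU kinematics
#' against optical motion capture: zero-lag low-pass filtering of the
#' reference, cross-correlation temporal alignment, linear resampling to a
#' common 100 Hz time base, and agreement statistics (RMSE, relative RMSE,
#' Pearson r, Bland-Altman bias and limits of agreement, ICC(2,1)).
#'
#' @name agreement
NULL

#' Zero-lag Butterworth low-pass filter
#'
#' Fourth-order Butterworth applied forward and backward (zero net phase,
#' squared magnitude response). The series is reflection-padded before
#' filtering to suppress edge transients.
#'
#' @param series numeric vector.
#' @param fs sampling frequency, Hz.
#' @param fc cutoff frequency, Hz (default 6).
#' @param order filter order (default 4).
#' @return filtered vector, same length.
#' @export
zero_lag_butterworth <- function(series, fs, fc = 6, order = 4) {
  if (fs <= 2 * fc) {
    rlang::abort("sampling rate must exceed twice the cutoff",
                 class = "gait_error_invalid_argument")
  }
  n <- length(series)
  if (n <= 3 * order) {
    rlang::abort("series too short for zero-lag filtering",
                 class = "gait_error_insufficient_data")
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  pad <- min(n - 1, max(3 * order, 100))
  x <- c(2 * series[1] - series[(pad + 1):2],
         series,
         2 * series[n] - series[(n - 1):(n - pad)])
  y <- signal::filter(bf, x)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(pad + 1):(pad + n)]
}

# normalized cross-correlation at integer lags
xcorr_lag <- function(test, reference, max_lag) {
  n <- min(length(test), length(reference))
  a <- test[seq_len(n)]; b <- reference[seq_len(n)]
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      x <- a[(1 + L):n]; y <- b[1:(n - L)]
    } else {
      x <- a[1:(n + L)]; y <- b[(1 - L):n]
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }, numeric(1))
  list(lags = lags, cc = cc, best = lags[which.max(cc)], peak = max(cc))
}

#' Temporal alignment of test and reference series by cross-correlation
#'
#' Finds the lag maximizing the normalized cross-correlation of an
#' alignment channel within a search range, shifts the test stream, and
#' resamples both to a common time base (default 100 Hz) by linear
#' interpolation. A positive estimated lag means the test stream leads the
#' reference.
#'
#' @param test,reference tibbles with columns `time` and `value`.
#' @param fs_out common output rate, Hz.
#' @param search lag search half-range, seconds.
#' @param min_peak minimum acceptable correlation peak.
#' @return list of class `aligned_pair`: `time`, `test`, `reference`
#'   (equal-length vectors on the common base) and `lag` (seconds).
#' @export
align_by_xcorr <- function(test, reference, fs_out = 100, search = 2,
                           min_peak = 0.5) {
  t0 <- max(min(test$time), min(reference$time))
  t1 <- min(max(test$time), max(reference$time))
  if (t1 - t0 < 2) {
    rlang::abort("need at least 2 s of overlap",
                 class = "gait_error_insufficient_data")
  }
  grid <- seq(t0, t1, by = 1 / fs_out)
  ts <- stats::approx(test$time, test$value, xout = grid)$y
  rs <- stats::approx(reference$time, reference$value, xout = grid)$y
  xc <- xcorr_lag(ts, rs, round(search * fs_out))
  if (xc$peak < min_peak) {
    rlang::abort(sprintf("correlation peak %.2f below %.2f", xc$peak,
                         min_peak),
                 class = "gait_error_alignment_failure")
  }
  lag <- -xc$best / fs_out
  # delay the test stream by the lag and re-interpolate both onto the
  # overlapping grid
  ts2 <- stats::approx(test$time + lag, test$value, xout = grid)$y
  keep <- !is.na(ts2) & !is.na(rs)
  structure(list(time = grid[keep], test = ts2[keep],
                 reference = rs[keep], lag = lag),
            class = "aligned_pair")
}

#' Agreement statistics for paired observations
#'
#' Computes RMSE, relative RMSE (percent of the reference mean), Pearson r,
#' Bland-Altman mean bias with 95% limits of agreement (bias +/- 1.96
#' sample SD of the differences), and the intraclass correlation
#' coefficient ICC(2,1) (two-way random effects, absolute agreement, single
#' measurement). Differences are `test - reference`.
#'
#' @param test,reference paired numeric vectors (n >= 3).
#' @return one-row tibble of class `agreement_report` with columns `n`,
#'   `rmse`, `rel_rmse_pct`, `pearson_r`, `bias`, `loa_low`, `loa_high`,
#'   `icc`; the per-pair differences and means are attached as attribute
#'   `bland_altman` for plotting. Zero-variance inputs yield `NA` for r and
#'   ICC with a warning.
#' @export
agreement_metrics <- function(test, reference) {
  if (length(test) != length(reference) || length(test) < 3) {
    rlang::abort("need >= 3 paired observations",
                 class = "gait_error_invalid_argument")
  }
  d <- test - reference
  rmse <- sqrt(mean(d^2))
  rel <- 100 * rmse / mean(reference)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sd_d
  if (stats::sd(test) == 0 || stats::sd(reference) == 0) {
    r <- NA_real_
    icc <- NA_real_
    rlang::warn("zero-variance input: r/ICC undefined",
                class = "gait_warning_undefined_statistic")
  } else {
    r <- stats::cor(test, reference)
    icc <- icc_2_1(test, reference)
  }
  out <- tibble::tibble(
    n = length(d), rmse = rmse, rel_rmse_pct = rel, pearson_r = r,
    bias = bias, loa_low = loa[1], loa_high = loa[2], icc = icc
  )
  class(out) <- c("agreement_report", class(out))
  attr(out, "bland_altman") <- tibble::tibble(
    mean = (test + reference) / 2, difference = d
  )
  out
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Computed from the two-way ANOVA mean squares of the n x 2 (subject x
#' rater) table: `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param test,reference paired vectors (the two "raters").
#' @export
icc_2_1 <- function(test, reference) {
  Y <- cbind(test, reference)
  n <- nrow(Y); k <- 2
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Relative RMSE in percent of a reference mean
#'
#' `100 * rmse / reference_mean`, the normalization used to report
#' spatiotemporal errors relative to the reference system's means.
#'
#' @param rmse root mean square error (units of the variable).
#' @param reference_mean reference-system mean (same units).
#' @export
relative_rmse <- function(rmse, reference_mean) {
  100 * rmse / reference_mean
}

#' Reference spatiotemporal comparison table
#'
#' The packaged reference table of spatiotemporal agreement values
#' (reference-system means and RMSEs for gait cycle, step length, stride
#' length and walking velocity) shipped under `extdata`; used to exercise
#' the relative-RMSE arithmetic.
#'
#' @return tibble with columns `parameter`, `unit`, `omc_mean`, `rmse`,
#'   `published_rel_rmse_pct`.
#' @export
spatiotemporal_reference <- function() {
  path <- system.file("extdata", "spatiotemporal_reference.csv",
                      package = "gaitnet")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
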