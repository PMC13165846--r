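#' Three-stage cascaded preprocessing filter
#'
#' On-board-style per-channel preprocessing applied before orientation
#' fusion: (1) a clipping filter that clamps samples to the sensor
#' full-scale range, (2) a sliding median filter that removes isolated
#' outliers, and (3) a sliding average filter that smooths residual
#' fluctuations. Window lengths default to 5 samples (25 ms at 200 Hz),
#' short enough to preserve heel-strike impulse features.
#'
#' @param clip_low,clip_high clamp limits in the channel's physical units.
#' @param median_window,mean_window odd window lengths in samples (>= 1).
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(clip_low = -Inf, clip_high = Inf,
                           median_window = 5, mean_window = 5) {
  if (clip_low >= clip_high) {
    rlang::abort("clip_low must be below clip_high",
                 class = "gait_error_invalid_argument")
  }
  for (w in c(median_window, mean_window)) {
    if (w < 1 || w %% 2 == 0) {
      rlang::abort("windows must be odd and >= 1",
                   class = "gait_error_invalid_argument")
    }
  }
  structure(list(clip_low = clip_low, clip_high = clip_high,
                 median_window = median_window, mean_window = mean_window),
            class = "cascade_config")
}

# running statistics with shrinking windows at the boundaries, so no
# fabricated samples enter downstream event detection

running_mean <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

running_median <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half <- (window - 1) / 2
  out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  for (i in seq_len(min(half, n))) {
    out[i] <- stats::median(x[1:min(n, i + half)])
    out[n - i + 1] <- stats::median(x[max(1, n - i + 1 - half):n])
  }
  out
}

#' Apply the cascaded clip -> median -> mean filter to one channel
#'
#' @param series numeric vector, one channel of one node.
#' @param cfg `cascade_config`.
#' @return filtered vector of the same length.
#' @export
cascade_filter <- function(series, cfg = cascade_config()) {
  if (length(series) < max(cfg$median_window, cfg$mean_window)) {
    rlang::abort("series shorter than the filter window",
                 class = "gait_error_insufficient_data")
  }
  x <- pmin(pmax(series, cfg$clip_low), cfg$clip_high)
  x <- running_median(x, cfg$median_window)
  running_mean(x, cfg$mean_window)
}

#' Default cascade configurations for the IMU channels
#'
#' Clip limits follow the sensor full-scale ranges (+/-8 g accelerometer,
#' +/-1000 deg/s gyroscope) converted to SI; the magnetometer is not clipped.
#'
#' @return named list of `cascade_config` objects for `gyro`, `accel`, `mag`.
#' @export
default_cascade_configs <- function() {
  list(
    gyro = cascade_config(-1000 * pi / 180, 1000 * pi / 180),
    accel = cascade_config(-8 * STANDARD_GRAVITY, 8 * STANDARD_GRAVITY),
    mag = cascade_config()
  )
}

# apply the cascade to every signal channel of a long-format trial tibble
preprocess_trial <- function(trial, configs = default_cascade_configs()) {
  chans <- list(gyro = c("gx", "gy", "gz"),
                accel = c("ax", "ay", "az"),
                mag = c("mx", "my", "mz"))
  dplyr::group_modify(dplyr::group_by(trial, .data$node), function(df, key) {
    for (grp in names(chans)) {
      for (ch in chans[[grp]]) {
        df[[ch]] <- cascade_filter(df[[ch]], configs[[grp]])
      }
    }
    df
  }) |> dplyr::ungroup()
}
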