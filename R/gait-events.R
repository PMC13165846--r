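#' Adaptive heel-strike / toe-off detection
#'
#' Gait events are detected from each foot node with a dual-feature rule:
#' candidate heel strikes (HS) are local maxima of the global-frame vertical
#' acceleration (gravity removed) above an individualized peak threshold,
#' candidate toe offs (TO) local minima below a valley threshold, and each
#' candidate must be confirmed by a matching zero crossing of the sagittal
#' angular velocity within +/-50 ms (downward for HS, upward for TO).
#' Thresholds are individualized as 0.6 times the mean peak/valley
#' amplitude over the first three stable gait cycles; before that
#' initialization completes, conservative bootstrap thresholds are used.
#'
#' @name gait_events
NULL

#' Threshold set for event detection
#'
#' @param peak,valley detection thresholds, m/s^2 (peak > 0 > valley once
#'   initialized; the bootstrap defaults are +/-2 m/s^2).
#' @param coefficient scaling coefficient applied to the mean extremum
#'   amplitudes of the initialization cycles.
#' @param n_init_cycles stable cycles required before individualization.
#' @param initialized whether the thresholds are individualized.
#' @export
threshold_set <- function(peak = 2, valley = -2, coefficient = 0.6,
                          n_init_cycles = 3, initialized = FALSE) {
  if (coefficient <= 0 || coefficient > 1) {
    rlang::abort("coefficient must be in (0, 1]",
                 class = "gait_error_invalid_argument")
  }
  if (initialized && !(peak > 0 && valley < 0)) {
    rlang::abort("initialized thresholds need peak > 0 > valley",
                 class = "gait_error_invalid_argument")
  }
  structure(list(peak = peak, valley = valley, coefficient = coefficient,
                 n_init_cycles = n_init_cycles, initialized = initialized),
            class = "threshold_set")
}

#' Individualize detection thresholds from initial-cycle extrema
#'
#' @param peak_amplitudes,valley_amplitudes candidate extremum amplitudes
#'   (m/s^2) from the first stable cycles; signed means are used.
#' @param thresholds current `threshold_set` (supplies the coefficient and
#'   the required cycle count).
#' @return initialized `threshold_set`.
#' @export
initialize_thresholds <- function(peak_amplitudes, valley_amplitudes,
                                  thresholds = threshold_set()) {
  k <- thresholds$n_init_cycles
  if (length(peak_amplitudes) < k || length(valley_amplitudes) < k) {
    rlang::abort(
      sprintf("need extrema from %d stable cycles to initialize", k),
      class = "gait_error_initialization_incomplete"
    )
  }
  threshold_set(
    peak = thresholds$coefficient * mean(peak_amplitudes),
    valley = thresholds$coefficient * mean(valley_amplitudes),
    coefficient = thresholds$coefficient,
    n_init_cycles = k,
    initialized = TRUE
  )
}

# local extrema of x with a +/-half_window sample neighbourhood
local_extrema <- function(x, half_window, maxima = TRUE) {
  n <- length(x)
  s <- if (maxima) x else -x
  idx <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_window); hi <- min(n, i + half_window)
    if (s[i] >= max(s[lo:hi]) && any(s[lo:hi] < s[i])) idx <- c(idx, i)
  }
  idx
}

# does omega cross zero in the given direction within the index window?
has_zero_crossing <- function(omega, centre, half_win, downward,
                              eps = 1e-3) {
  lo <- max(1, centre - half_win)
  hi <- min(length(omega), centre + half_win)
  w <- omega[lo:hi]
  if (length(w) < 2) return(FALSE)
  if (downward) {
    any(w[-length(w)] > eps & w[-1] <= eps)
  } else {
    any(w[-length(w)] < -eps & w[-1] >= -eps)
  }
}

#' Detect heel-strike and toe-off events
#'
#' @param a_vert vertical acceleration series (global frame, gravity
#'   removed), m/s^2.
#' @param omega_sag sagittal (mediolateral-axis) angular velocity of the
#'   foot segment, rad/s; same length and time base as `a_vert`.
#' @param thresholds `threshold_set`. When uninitialized, the function
#'   first detects with the bootstrap thresholds, individualizes from the
#'   first `n_init_cycles` stable cycles, and re-detects with the
#'   individualized thresholds.
#' @param fs sampling frequency, Hz.
#' @param side "left" or "right" (annotation only).
#' @param time optional time stamps for the samples (defaults to
#'   `(0:(n-1))/fs`).
#' @param extremum_window half-width of the local-extremum neighbourhood,
#'   seconds.
#' @param min_separation minimum spacing between events of the same type,
#'   seconds.
#' @param zc_window zero-crossing verification half-window, seconds.
#' @return tibble with columns `time`, `type` ("HS"/"TO"), `side`, `index`,
#'   ordered in time, alternating HS/TO; the individualized `threshold_set`
#'   is attached as attribute `thresholds`.
#' @export
detect_events <- function(a_vert, omega_sag, thresholds = threshold_set(),
                          fs = 200, side = "left", extremum_window = 0.25,
                          min_separation = 0.3, zc_window = 0.05,
                          time = NULL) {
  if (length(a_vert) != length(omega_sag)) {
    rlang::abort("a_vert and omega_sag must have the same length",
                 class = "gait_error_invalid_argument")
  }
  if (is.null(time)) time <- (seq_along(a_vert) - 1) / fs
  detect_once <- function(thr) {
    half_ext <- round(extremum_window * fs)
    half_zc <- round(zc_window * fs)
    min_sep <- round(min_separation * fs)

    cand <- function(maxima) {
      idx <- local_extrema(a_vert, half_ext, maxima = maxima)
      if (maxima) idx <- idx[a_vert[idx] > thr$peak]
      else idx <- idx[a_vert[idx] < thr$valley]
      dir_down <- maxima  # HS: downward crossing; TO: upward
      idx[vapply(idx, function(i) {
        has_zero_crossing(omega_sag, i, half_zc, downward = dir_down)
      }, logical(1))]
    }
    hs <- cand(TRUE); to <- cand(FALSE)

    # merge, enforce minimum separation per type keeping stronger extrema
    thin <- function(idx, strength) {
      keep <- integer(0)
      for (i in idx[order(-strength[idx])]) {
        if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
      }
      sort(keep)
    }
    hs <- thin(hs, a_vert)
    to <- thin(to, -a_vert)

    ev <- rbind(
      data.frame(index = hs, type = rep("HS", length(hs)),
                 strength = a_vert[hs]),
      data.frame(index = to, type = rep("TO", length(to)),
                 strength = -a_vert[to])
    )
    ev <- ev[order(ev$index), , drop = FALSE]
    # enforce alternation: among consecutive events of the same type keep
    # the stronger extremum
    if (nrow(ev) > 1) {
      repeat {
        same <- which(ev$type[-1] == ev$type[-nrow(ev)])
        if (length(same) == 0) break
        i <- same[1]
        drop_row <- if (ev$strength[i] >= ev$strength[i + 1]) i + 1 else i
        ev <- ev[-drop_row, , drop = FALSE]
      }
    }
    ev
  }

  ev <- detect_once(thresholds)
  if (!thresholds$initialized && nrow(ev) > 0) {
    cyc <- validate_cycles(tibble::tibble(
      time = time[ev$index], type = ev$type, side = side, index = ev$index
    ))
    stable <- cyc[cyc$stable, , drop = FALSE]
    k <- thresholds$n_init_cycles
    if (nrow(stable) >= k) {
      first_k <- stable[seq_len(k), ]
      ev_time <- time[ev$index]
      hs_idx <- ev$index[match(first_k$start, ev_time)]
      to_idx <- ev$index[match(first_k$to, ev_time)]
      thresholds <- initialize_thresholds(a_vert[hs_idx], a_vert[to_idx],
                                          thresholds)
      ev <- detect_once(thresholds)
    }
  }

  out <- tibble::tibble(
    time = time[ev$index],
    type = ev$type,
    side = side,
    index = ev$index
  )
  attr(out, "thresholds") <- thresholds
  out
}

#' Build gait cycles from an event timeline and flag stability
#'
#' Cycles run HS -> TO -> next HS on one side. A cycle is stable when its
#' internal ordering is physiological (HS < TO < next HS) and its duration
#' deviates less than +/-20% from the immediately preceding cycle (the
#' first cycle is provisionally stable).
#'
#' @param events tibble as returned by [detect_events()] (single side).
#' @param duration_tol relative duration deviation tolerance.
#' @return tibble with columns `side`, `start`, `to`, `end`, `duration`,
#'   `stable`.
#' @export
validate_cycles <- function(events, duration_tol = 0.2) {
  ev <- events[order(events$time), , drop = FALSE]
  hs <- ev[ev$type == "HS", , drop = FALSE]
  out <- list()
  prev_duration <- NA_real_
  if (nrow(hs) >= 2) {
    for (i in seq_len(nrow(hs) - 1)) {
      t0 <- hs$time[i]; t1 <- hs$time[i + 1]
      tos <- ev$time[ev$type == "TO" & ev$time > t0 & ev$time < t1]
      to_time <- if (length(tos) == 1) tos else NA_real_
      duration <- t1 - t0
      ok_order <- !is.na(to_time)
      ok_duration <- is.na(prev_duration) ||
        abs(duration - prev_duration) <= duration_tol * prev_duration
      stable <- ok_order && ok_duration
      out[[i]] <- tibble::tibble(
        side = hs$side[i], start = t0, to = to_time, end = t1,
        duration = duration, stable = stable
      )
      if (ok_order) prev_duration <- duration
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(side = character(), start = numeric(),
                          to = numeric(), end = numeric(),
                          duration = numeric(), stable = logical()))
  }
  dplyr::bind_rows(out)
}
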