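#' Foot trajectory reconstruction with zero-velocity updates
#'
#' Foot-mounted accelerometer data are rotated to the global frame, gravity
#' is removed, and velocity/position are obtained by trapezoidal
#' integration. Integration drift is cancelled with a zero-velocity update
#' (ZUPT) strategy: within each stance, the quiet foot-flat sub-interval is
#' located, and the linear velocity-drift ramp that zeroes velocity at
#' consecutive foot-flat midpoints is subtracted before integrating to
#' position.
#'
#' @name trajectory
NULL

#' Detect foot-flat (mid-stance) intervals
#'
#' Within each stance window `[HS + guard, TO - guard]`, finds the longest
#' sub-interval in which the angular-rate norm stays below `omega_max` and
#' the acceleration magnitude stays within `accel_tol` of gravity, sustained
#' for at least `min_duration`.
#'
#' @param stream foot node tibble (columns `time`, `gx..gz`, `ax..az`).
#' @param events event tibble for this side ([detect_events()]).
#' @param omega_max angular-rate threshold, rad/s (default 20 deg/s).
#' @param accel_tol acceleration-magnitude tolerance about g, m/s^2.
#' @param guard time excluded after HS and before TO, seconds.
#' @param min_duration minimum quiet duration, seconds.
#' @param g gravity magnitude, m/s^2.
#' @return tibble with columns `start`, `end`, `mid` (seconds). Stances with
#'   no qualifying interval are dropped with a warning (missing-zupt).
#' @export
detect_foot_flat <- function(stream, events, omega_max = 20 * pi / 180,
                             accel_tol = 0.5, guard = 0.05,
                             min_duration = 0.05, g = STANDARD_GRAVITY) {
  tt <- stream$time
  omega_norm <- sqrt(stream$gx^2 + stream$gy^2 + stream$gz^2)
  acc_dev <- abs(sqrt(stream$ax^2 + stream$ay^2 + stream$az^2) - g)
  quiet <- omega_norm < omega_max & acc_dev < accel_tol

  hs <- events$time[events$type == "HS"]
  to <- events$time[events$type == "TO"]
  out <- list()
  missing <- 0
  for (h in hs) {
    nxt <- to[to > h]
    if (length(nxt) == 0) next
    t0 <- h + guard; t1 <- nxt[1] - guard
    idx <- which(tt >= t0 & tt <= t1)
    if (length(idx) == 0) { missing <- missing + 1; next }
    q <- quiet[idx]
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (length(runs) == 0) { missing <- missing + 1; next }
    lens <- tt[idx[ends[runs]]] - tt[idx[starts[runs]]]
    best <- runs[which.max(lens)]
    if (max(lens) < min_duration) { missing <- missing + 1; next }
    s <- tt[idx[starts[best]]]; e <- tt[idx[ends[best]]]
    out[[length(out) + 1]] <- tibble::tibble(start = s, end = e,
                                             mid = (s + e) / 2)
  }
  if (missing > 0) {
    rlang::warn(sprintf("%d stance(s) without a foot-flat interval", missing),
                class = "gait_warning_missing_zupt")
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          mid = numeric()))
  }
  dplyr::bind_rows(out)
}

# trapezoidal cumulative integral of each column of Y over t
cumtrapz_cols <- function(t, Y) {
  dt <- diff(t)
  inc <- (Y[-1, , drop = FALSE] + Y[-nrow(Y), , drop = FALSE]) / 2 * dt
  rbind(0, apply(inc, 2, cumsum))
}

#' Reconstruct the global-frame foot trajectory
#'
#' @param stream foot node tibble with calibrated accelerometer columns.
#' @param orientation orientation tibble ([estimate_orientation()]) aligned
#'   sample-by-sample with `stream`.
#' @param intervals foot-flat intervals ([detect_foot_flat()]). With no
#'   intervals the uncorrected integration is returned flagged
#'   (`zupt_applied = FALSE`) with a warning rather than silently trusted.
#' @param events optional event tibble; when given, positions at HS samples
#'   are recorded as initial-contact positions.
#' @param g gravity magnitude, m/s^2.
#' @return tibble (`time`, `vx vy vz`, `px py pz`) of class
#'   `foot_trajectory` with attributes `intervals`, `contacts` (tibble of
#'   HS times and positions) and `zupt_applied`.
#' @export
reconstruct_trajectory <- function(stream, orientation, intervals,
                                   events = NULL, g = STANDARD_GRAVITY) {
  tt <- stream$time
  Q <- cbind(orientation$qw, orientation$qx, orientation$qy, orientation$qz)
  A_s <- cbind(stream$ax, stream$ay, stream$az)
  A_g <- quat_rotate_rows(Q, A_s)
  A_g[, 2] <- A_g[, 2] - g   # remove gravity reaction (Y up)

  V <- cumtrapz_cols(tt, A_g)
  zupt <- nrow(intervals) >= 1
  if (!zupt) {
    rlang::warn("no foot-flat intervals: trajectory integrated uncorrected",
                class = "gait_warning_uncorrected_integration")
  } else {
    mids <- vapply(intervals$mid, function(m) which.min(abs(tt - m)),
                   integer(1))
    # the first and last samples are implicit anchors: integration starts
    # at rest and recordings end standing, so velocity is zero there too
    anchors <- sort(unique(c(1L, mids, nrow(V))))
    for (k in 1:3) {
      drift <- stats::approx(tt[anchors], V[anchors, k], xout = tt)$y
      V[, k] <- V[, k] - drift
    }
  }
  P <- cumtrapz_cols(tt, V)

  contacts <- NULL
  if (!is.null(events)) {
    hs <- events[events$type == "HS", , drop = FALSE]
    if (nrow(hs) > 0) {
      idx <- vapply(hs$time, function(h) which.min(abs(tt - h)), integer(1))
      contacts <- tibble::tibble(
        time = hs$time, side = hs$side,
        x = P[idx, 1], y = P[idx, 2], z = P[idx, 3]
      )
    }
  }

  out <- tibble::tibble(time = tt, vx = V[, 1], vy = V[, 2], vz = V[, 3],
                        px = P[, 1], py = P[, 2], pz = P[, 3])
  class(out) <- c("foot_trajectory", class(out))
  attr(out, "intervals") <- intervals
  attr(out, "contacts") <- contacts
  attr(out, "zupt_applied") <- zupt
  out
}

#' Spatiotemporal gait parameters from both feet
#'
#' The walking axis is the principal horizontal direction of all
#' initial-contact positions. Stride length is the displacement between
#' successive same-side initial contacts projected on that axis (set
#' `stride_method = "norm"` for the full Euclidean displacement — equal for
#' perfectly straight walking and never smaller). Step width is the
#' mediolateral separation of contralateral contacts, cadence
#' `(n_step - 1)/(t_end - t_start) * 60` counting both feet, and walking
#' velocity the net walking-axis displacement over elapsed time.
#'
#' @param left,right `foot_trajectory` objects with contact attributes.
#' @param events combined event tibble (both sides) for cycle timing.
#' @param stride_method "projection" (default) or "norm".
#' @param initial_stance_m assumed mediolateral separation of the feet
#'   during the initial quiet standing. Each foot's trajectory is
#'   dead-reckoned in its own frame, so the absolute lateral offset between
#'   the feet is unobservable; step width is reported relative to this
#'   standing separation plus the measured relative mediolateral
#'   displacement.
#' @return list of class `spatiotemporal` with `strides` (per-stride tibble)
#'   and `summary` (one-row tibble: `stride_length_m`, `step_width_m`,
#'   `cadence_spm`, `velocity_ms`, `cycle_time_s`, `n_steps`).
#' @export
spatiotemporal_params <- function(left, right, events,
                                  stride_method = c("projection", "norm"),
                                  initial_stance_m = 0.1) {
  stride_method <- match.arg(stride_method)
  cl <- attr(left, "contacts"); cr <- attr(right, "contacts")
  if (is.null(cl) || is.null(cr) || nrow(cl) < 2 || nrow(cr) < 2) {
    rlang::abort("need at least 2 initial contacts per side",
                 class = "gait_error_insufficient_strides")
  }
  contacts <- dplyr::arrange(dplyr::bind_rows(cl, cr), .data$time)

  # principal horizontal direction of the contact cloud = walking axis
  H <- cbind(contacts$x, contacts$z)
  Hc <- sweep(H, 2, colMeans(H))
  ax <- eigen(crossprod(Hc), symmetric = TRUE)$vectors[, 1]
  if (sum(ax * (H[nrow(H), ] - H[1, ])) < 0) ax <- -ax
  walk_dir <- c(ax[1], 0, ax[2])
  ml_dir <- c(walk_dir[3], 0, -walk_dir[1])  # horizontal perpendicular

  along <- function(df) df$x * walk_dir[1] + df$z * walk_dir[3]
  across <- function(df) df$x * ml_dir[1] + df$z * ml_dir[3]

  stride_tbl <- function(cc, side) {
    n <- nrow(cc)
    if (n < 2) return(NULL)
    d_proj <- diff(along(cc))
    d_norm <- sqrt(diff(cc$x)^2 + diff(cc$y)^2 + diff(cc$z)^2)
    tibble::tibble(
      side = side,
      t_start = cc$time[-n], t_end = cc$time[-1],
      stride_length = if (stride_method == "projection") d_proj else d_norm,
      stride_length_norm = d_norm
    )
  }
  strides <- dplyr::bind_rows(stride_tbl(cl, "left"), stride_tbl(cr, "right"))

  # step width: each contact vs the preceding contralateral contact; the
  # unobservable standing separation enters as a constant offset
  acr <- across(contacts) + ifelse(contacts$side == "right",
                                   initial_stance_m, 0)
  sw <- numeric(0)
  for (i in seq_len(nrow(contacts))[-1]) {
    prev <- max(which(contacts$side[seq_len(i - 1)] != contacts$side[i]),
                -Inf)
    if (is.finite(prev)) {
      sw <- c(sw, abs(acr[i] - acr[prev]))
    }
  }

  n_step <- nrow(contacts)
  t_start <- contacts$time[1]; t_end <- contacts$time[n_step]
  cadence <- (n_step - 1) / (t_end - t_start) * 60
  dz <- abs(along(contacts[n_step, ]) - along(contacts[1, ]))
  velocity <- dz / (t_end - t_start)

  cycles <- validate_cycles(events[events$side == "left", , drop = FALSE])
  cycle_time <- if (nrow(cycles) > 0) mean(cycles$duration) else NA_real_

  structure(list(
    strides = strides,
    summary = tibble::tibble(
      stride_length_m = mean(strides$stride_length),
      step_width_m = mean(sw),
      cadence_spm = cadence,
      velocity_ms = velocity,
      cycle_time_s = cycle_time,
      n_steps = n_step
    )
  ), class = "spatiotemporal")
}

#' @export
print.spatiotemporal <- function(x, ...) {
  cat("Spatiotemporal gait parameters\n")
  print(x$summary)
  invisible(x)
}
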