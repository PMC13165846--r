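#' Parameter-adaptive nonlinear complementary filter
#'
#' Orientation estimation fuses gyroscope integration with gravity and
#' magnetic-field vector observations through a PI feedback on a
#' cross-product error (a Mahony-style nonlinear complementary filter). Two
#' gains adapt during walking:
#'
#' * the proportional gain follows a Gaussian schedule in the deviation of
#'   the measured acceleration magnitude from standard gravity,
#'   `Kp = Kp0 * exp(-alpha * (|a| - g)^2)`, so accelerometer corrections are
#'   attenuated during dynamic phases and fully trusted under quasi-static
#'   conditions;
#' * the integral gain switches with the detected gait phase — a high value
#'   during stance (reliable gravity reference, strong drift compensation)
#'   and a low value during swing.
#'
#' @name orientation
NULL

#' Filter parameters for the adaptive complementary filter
#'
#' Defaults are the calibrated values used throughout: baseline proportional
#' gain 1.8, shaping parameter 0.5 (units 1/(m/s^2)^2 on the squared
#' magnitude deviation), stance integral gain 0.05, swing integral gain
#' 0.005.
#'
#' @param kp0 baseline proportional gain (dimensionless).
#' @param alpha shaping parameter controlling sensitivity to acceleration
#'   disturbance.
#' @param ki_high,ki_low integral gains for stance and swing.
#' @param g standard gravity, m/s^2.
#' @param b_n magnetic reference direction in the global frame (unit
#'   vector); the default has a 60-degree downward inclination in the
#'   sagittal (vertical/forward) plane. Errors in this choice affect only
#'   heading, not sagittal angles.
#' @param e_int_clamp componentwise anti-windup clamp on the integrated
#'   error vector.
#' @param e_int_gate conditional-integration anti-windup: the integral only
#'   accumulates while the error-vector norm is below this gate, so large
#'   alignment transients (which the proportional term handles) do not wind
#'   the integral up and leave a slowly draining residual.
#' @return list of class `ncf_params`.
#' @export
ncf_params <- function(kp0 = 1.8, alpha = 0.5, ki_high = 0.05,
                       ki_low = 0.005, g = STANDARD_GRAVITY,
                       b_n = c(0, -sin(pi / 3), cos(pi / 3)),
                       e_int_clamp = 1, e_int_gate = 0.2) {
  if (any(c(kp0, alpha, ki_high, ki_low) <= 0) || ki_high <= ki_low) {
    rlang::abort("gains must be positive with ki_high > ki_low",
                 class = "gait_error_invalid_argument")
  }
  b_n <- b_n / sqrt(sum(b_n^2))
  structure(list(kp0 = kp0, alpha = alpha, ki_high = ki_high,
                 ki_low = ki_low, g = g, b_n = b_n,
                 e_int_clamp = e_int_clamp, e_int_gate = e_int_gate),
            class = "ncf_params")
}

#' Acceleration-adaptive proportional gain
#'
#' `Kp = Kp0 * exp(-alpha * (a_mag - g)^2)`: equal to `Kp0` exactly when the
#' measured magnitude equals gravity, strictly decreasing and symmetric in
#' the deviation.
#'
#' @param a_mag magnitude of the measured acceleration, m/s^2 (vectorized).
#' @param params `ncf_params`.
#' @export
adaptive_kp <- function(a_mag, params = ncf_params()) {
  params$kp0 * exp(-params$alpha * (a_mag - params$g)^2)
}

#' Phase-scheduled integral gain
#'
#' @param phase character vector: "stance", "swing" or "uninitialized".
#'   Before event-detection thresholds are initialized the trial starts with
#'   quiet standing, so the uninitialized phase uses the stance (high) gain.
#' @param params `ncf_params`.
#' @export
select_ki <- function(phase, params = ncf_params()) {
  ifelse(phase == "swing", params$ki_low, params$ki_high)
}

#' Composite vector-observation error
#'
#' Cross-product mismatch between the normalized accelerometer and
#' magnetometer measurements and the gravity / magnetic reference directions
#' projected into the sensor frame by the current orientation estimate:
#' `e = a_hat x v_g + m_hat x v_b`.
#'
#' @param q current orientation (sensor to global unit quaternion).
#' @param a_meas accelerometer reading, sensor frame, m/s^2.
#' @param m_meas magnetometer reading, sensor frame (any scale).
#' @param params `ncf_params`.
#' @return length-3 error vector (dimensionless).
#' @export
error_vector <- function(q, a_meas, m_meas, params = ncf_params()) {
  na <- sqrt(sum(a_meas^2)); nm <- sqrt(sum(m_meas^2))
  if (na == 0 || nm == 0) {
    rlang::abort("zero-norm vector observation",
                 class = "gait_error_unusable_sample")
  }
  a_hat <- a_meas / na
  m_hat <- m_meas / nm
  v_g <- quat_rotate_inv(q, c(0, 1, 0))       # gravity reaction, "up"
  v_b <- quat_rotate_inv(q, params$b_n)
  cross3(a_hat, v_g) + cross3(m_hat, v_b)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Initial filter state
#'
#' @param q initial orientation quaternion.
#' @param b gyro bias estimate (rad/s) subtracted at every step.
#' @return list of class `ncf_state` with fields `q`, `e_int`, `b`, `phase`.
#' @export
ncf_state <- function(q = quat_identity(), b = c(0, 0, 0)) {
  structure(list(q = q, e_int = c(0, 0, 0), b = b, phase = "uninitialized"),
            class = "ncf_state")
}

#' Single step of the adaptive complementary filter
#'
#' Computes the vector-observation error, accumulates the (clamped)
#' integral, forms the corrected rate
#' `omega_hat = omega_gyro - b + Kp * e + Ki * integral(e)` and advances the
#' quaternion one first-order integration step. A zero-norm accelerometer
#' or magnetometer sample degrades gracefully to a gyro-only update.
#'
#' @param state `ncf_state`.
#' @param gyro,accel,mag sensor-frame measurements (rad/s, m/s^2, any unit).
#' @param dt step, seconds.
#' @param phase gait phase label for the integral gain schedule.
#' @param params `ncf_params`.
#' @return updated `ncf_state`.
#' @export
ncf_step <- function(state, gyro, accel, mag, dt, phase = "uninitialized",
                     params = ncf_params()) {
  if (!all(is.finite(c(gyro, accel, mag)))) {
    rlang::abort("non-finite sample", class = "gait_error_invalid_argument")
  }
  ki <- select_ki(phase, params)
  # predict with the inertial terms, then correct against the vector
  # observations of this sample
  q_pred <- integrate_quat(state$q, gyro - state$b + ki * state$e_int, dt)
  e <- tryCatch(error_vector(q_pred, accel, mag, params),
                gait_error_unusable_sample = function(cnd) c(0, 0, 0))
  kp <- adaptive_kp(sqrt(sum(accel^2)), params)
  e_int <- if (sqrt(sum(e^2)) <= params$e_int_gate) {
    pmin(pmax(state$e_int + e * dt, -params$e_int_clamp),
         params$e_int_clamp)
  } else state$e_int
  state$q <- integrate_quat(q_pred, kp * e, dt)
  state$e_int <- e_int
  state$phase <- phase
  state
}

#' Closed-form static orientation from accelerometer and magnetometer
#'
#' TRIAD-style construction: the measured gravity reaction fixes the sensor
#' "up" direction, the magnetometer fixes heading about it. Used to
#' initialize the filter from the first static second of a trial.
#'
#' @param a_mean,m_mean mean accelerometer / magnetometer readings over a
#'   static window (sensor frame).
#' @param params `ncf_params` (for the magnetic reference).
#' @return unit quaternion (sensor to global).
#' @export
static_orientation <- function(a_mean, m_mean, params = ncf_params()) {
  up_g <- c(0, 1, 0)
  e_g <- cross3(up_g, params$b_n); e_g <- e_g / sqrt(sum(e_g^2))
  w1 <- a_mean / sqrt(sum(a_mean^2))
  e_s <- cross3(w1, m_mean)
  n <- sqrt(sum(e_s^2))
  if (n < 1e-12) {
    rlang::abort("magnetometer parallel to gravity; heading unobservable",
                 class = "gait_error_degenerate_orientation")
  }
  w2 <- e_s / n
  w3 <- cross3(w1, w2)
  v3 <- cross3(up_g, e_g)
  # columns: sensor-frame triad expressed in both frames -> R maps sensor
  # coordinates of the triad onto global coordinates
  Ws <- cbind(w1, w2, w3)
  Vg <- cbind(up_g, e_g, v3)
  matrix_to_quat(Vg %*% t(Ws))
}

#' Batch orientation estimation for one node stream
#'
#' Causal pass of [ncf_step()] over a preprocessed, calibrated node stream.
#' The initial orientation comes from a closed-form accelerometer +
#' magnetometer alignment over the first static second; phase labels come
#' from an optional per-sample phase vector (derived from the ipsilateral
#' foot's event timeline by the pipeline).
#'
#' This loop is written with unrolled quaternion arithmetic on plain
#' doubles: at 200 Hz a 15 s trial is ~3000 steps per node and the unrolled
#' form keeps the whole seven-node pipeline interactive.
#'
#' @param stream tibble with columns `time`, `gx gy gz` (rad/s),
#'   `ax ay az` (m/s^2), `mx my mz`.
#' @param phase optional character vector (length `nrow(stream)`) of
#'   "stance"/"swing"/"uninitialized" labels.
#' @param params `ncf_params`.
#' @param gyro_bias length-3 gyro bias (rad/s), subtracted each step.
#' @param init_window seconds of leading data used for the static
#'   initial-orientation fix.
#' @param adaptive set `FALSE` to run the conventional fixed-gain filter
#'   (`Kp = kp0`, `Ki = ki_high` throughout) for ablation comparisons.
#' @return tibble with columns `time`, `qw`, `qx`, `qy`, `qz`.
#' @export
estimate_orientation <- function(stream, phase = NULL, params = ncf_params(),
                                 gyro_bias = c(0, 0, 0), init_window = 1,
                                 adaptive = TRUE) {
  n <- nrow(stream)
  if (is.null(n) || n < 2) {
    rlang::abort("stream too short", class = "gait_error_insufficient_data")
  }
  tt <- stream$time
  G <- cbind(stream$gx, stream$gy, stream$gz)
  A <- cbind(stream$ax, stream$ay, stream$az)
  M <- cbind(stream$mx, stream$my, stream$mz)
  if (!all(is.finite(G)) || !all(is.finite(A)) || !all(is.finite(M))) {
    rlang::abort("non-finite samples in stream",
                 class = "gait_error_invalid_argument")
  }
  if (is.null(phase)) phase <- rep("uninitialized", n)
  ki_vec <- if (adaptive) select_ki(phase, params) else
    rep(params$ki_high, n)

  i0 <- which(tt <= tt[1] + init_window)
  q0 <- static_orientation(colMeans(A[i0, , drop = FALSE]),
                           colMeans(M[i0, , drop = FALSE]), params)

  bnx <- params$b_n[1]; bny <- params$b_n[2]; bnz <- params$b_n[3]
  clamp <- params$e_int_clamp
  gate2 <- params$e_int_gate^2
  kp0 <- params$kp0; alpha <- params$alpha; gref <- params$g
  bx <- gyro_bias[1]; by <- gyro_bias[2]; bz <- gyro_bias[3]

  Q <- matrix(0, n, 4)
  qw <- q0[1]; qx <- q0[2]; qy <- q0[3]; qz <- q0[4]
  Q[1, ] <- c(qw, qx, qy, qz)
  eix <- 0; eiy <- 0; eiz <- 0

  for (i in 2:n) {
    dt <- tt[i] - tt[i - 1]

    # predict: advance with the trapezoidal gyro rate (bias removed, plus
    # the integral correction), which keeps the integration error third
    # order in dt for oscillatory motion
    wx <- 0.5 * (G[i, 1] + G[i - 1, 1]) - bx + ki_vec[i] * eix
    wy <- 0.5 * (G[i, 2] + G[i - 1, 2]) - by + ki_vec[i] * eiy
    wz <- 0.5 * (G[i, 3] + G[i - 1, 3]) - bz + ki_vec[i] * eiz
    hdt <- 0.5 * dt
    nqw <- qw + hdt * (-qx * wx - qy * wy - qz * wz)
    nqx <- qx + hdt * (qw * wx + qy * wz - qz * wy)
    nqy <- qy + hdt * (qw * wy - qx * wz + qz * wx)
    nqz <- qz + hdt * (qw * wz + qx * wy - qy * wx)
    nn <- sqrt(nqw * nqw + nqx * nqx + nqy * nqy + nqz * nqz)
    qw <- nqw / nn; qx <- nqx / nn; qy <- nqy / nn; qz <- nqz / nn

    # correct: vector-observation error against the predicted orientation,
    # so the measurement at sample i is compared with the estimate at i
    ax <- A[i, 1]; ay <- A[i, 2]; az <- A[i, 3]
    mx <- M[i, 1]; my <- M[i, 2]; mz <- M[i, 3]
    na <- sqrt(ax * ax + ay * ay + az * az)
    nm <- sqrt(mx * mx + my * my + mz * mz)

    if (na > 0 && nm > 0) {
      ax <- ax / na; ay <- ay / na; az <- az / na
      mx <- mx / nm; my <- my / nm; mz <- mz / nm
      # gravity reference (0,1,0) into sensor frame via conjugate rotation
      vgx <- 2 * (qx * qy + qw * qz)
      vgy <- 1 - 2 * (qx * qx + qz * qz)
      vgz <- 2 * (qy * qz - qw * qx)
      # magnetic reference into sensor frame (R^T b_n)
      vbx <- (1 - 2 * (qy * qy + qz * qz)) * bnx +
        2 * (qx * qy + qw * qz) * bny + 2 * (qx * qz - qw * qy) * bnz
      vby <- 2 * (qx * qy - qw * qz) * bnx +
        (1 - 2 * (qx * qx + qz * qz)) * bny + 2 * (qy * qz + qw * qx) * bnz
      vbz <- 2 * (qx * qz + qw * qy) * bnx +
        2 * (qy * qz - qw * qx) * bny + (1 - 2 * (qx * qx + qy * qy)) * bnz
      ex <- (ay * vgz - az * vgy) + (my * vbz - mz * vby)
      ey <- (az * vgx - ax * vgz) + (mz * vbx - mx * vbz)
      ez <- (ax * vgy - ay * vgx) + (mx * vby - my * vbx)
    } else {
      ex <- 0; ey <- 0; ez <- 0
    }

    kp <- if (adaptive) kp0 * exp(-alpha * (na - gref)^2) else kp0
    if (ex * ex + ey * ey + ez * ez <= gate2) {
      eix <- min(max(eix + ex * dt, -clamp), clamp)
      eiy <- min(max(eiy + ey * dt, -clamp), clamp)
      eiz <- min(max(eiz + ez * dt, -clamp), clamp)
    }

    wx <- kp * ex; wy <- kp * ey; wz <- kp * ez
    nqw <- qw + hdt * (-qx * wx - qy * wy - qz * wz)
    nqx <- qx + hdt * (qw * wx + qy * wz - qz * wy)
    nqy <- qy + hdt * (qw * wy - qx * wz + qz * wx)
    nqz <- qz + hdt * (qw * wz + qx * wy - qy * wx)
    nn <- sqrt(nqw * nqw + nqx * nqx + nqy * nqy + nqz * nqz)
    qw <- nqw / nn; qx <- nqx / nn; qy <- nqy / nn; qz <- nqz / nn
    Q[i, ] <- c(qw, qx, qy, qz)
  }

  tibble::tibble(time = tt, qw = Q[, 1], qx = Q[, 2], qy = Q[, 3],
                 qz = Q[, 4])
}
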