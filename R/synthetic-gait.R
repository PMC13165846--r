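#' Synthetic gait simulator
#'
#' Generates ground-truth walking kinematics for a seven-segment pelvis and
#' lower-limb chain and synthesizes the corresponding ideal or noisy IMU
#' streams, so that every pipeline stage can be verified without hardware.
#'
#' The simulated trial mirrors a standard walkway protocol: quiet standing,
#' a steady straight walk at fixed cadence and stride length, quiet
#' standing again. Joint-angle waveforms are truncated Fourier series with
#' normal-gait magnitudes; foot trajectories are constructed analytically
#' so that each foot is exactly stationary during mid-stance (making
#' zero-velocity-update assumptions verifiable by construction) and carries
#' a short impact transient at heel strike and a push-off transient at toe
#' off, the signatures event detection relies on.
#'
#' @name synthetic_gait
NULL

#' Gait profile: the study conditions of a simulated trial
#'
#' Defaults describe comfortable-speed walking of a healthy adult on a
#' straight walkway: gait cycle 1.05 s (cadence ~114 steps/min), stride
#' 1.36 m (walking speed ~1.30 m/s), 12 cycles bounded by 2.5 s of quiet
#' standing, 200 Hz sampling, stance duty factor 0.6.
#'
#' @param cadence_spm steps per minute (both feet).
#' @param stride_m stride length, metres.
#' @param n_cycles complete gait cycles in the walk.
#' @param duty stance fraction of the cycle, in (0.5, 0.75).
#' @param step_width_m mediolateral distance between foot lines.
#' @param static_s quiet-standing duration before and after the walk.
#' @param fs sampling frequency, Hz.
#' @param swing_clearance_m peak swing foot lift.
#' @param impact_peak vertical acceleration magnitude of the heel-strike /
#'   push-off transients, m/s^2.
#' @param foot_pitch_deg amplitude of the foot sagittal-angle cycle.
#' @param hip_coef,knee_coef Fourier coefficients (degrees, clinical signs:
#'   flexion positive) as `list(a0, amp, phase)` giving
#'   `a0 + sum(amp[k] cos(2 pi k c + phase[k]))` over cycle phase `c`.
#' @param pelvis_tilt_amp_deg,pelvis_rot_amp_deg pelvic waveform amplitudes.
#' @param pelvis_height_m pelvic sensor height while standing.
#' @param pelvis_bob_m,pelvis_sway_m vertical / mediolateral pelvic
#'   translation oscillation amplitudes.
#' @param thigh_m,shank_m segment lengths.
#' @param sensor_drop_m distance of the thigh/shank sensors below their
#'   proximal joint centres.
#' @return list of class `gait_profile`.
#' @export
gait_profile <- function(cadence_spm = 2 * 60 / 1.05, stride_m = 1.36,
                         n_cycles = 12, duty = 0.6, step_width_m = 0.10,
                         static_s = 2.5, fs = 200,
                         swing_clearance_m = 0.04, impact_peak = 12,
                         foot_pitch_deg = 10,
                         hip_coef = list(a0 = 12,
                                         amp = c(20, 2.5, 1),
                                         phase = c(0.44, 3.5, 1.0)),
                         knee_coef = list(a0 = 22,
                                          amp = c(12, 15, 4),
                                          phase = c(-0.3, 2.1, 0.9)),
                         pelvis_tilt_amp_deg = 2, pelvis_rot_amp_deg = 4,
                         pelvis_height_m = 1.0, pelvis_bob_m = 0.015,
                         pelvis_sway_m = 0.02, thigh_m = 0.42,
                         shank_m = 0.42, sensor_drop_m = 0.28) {
  if (duty <= 0.5 || duty >= 0.75) {
    rlang::abort("duty factor must be in (0.5, 0.75)",
                 class = "gait_error_infeasible_profile")
  }
  if (stride_m > 1.8 * (thigh_m + shank_m)) {
    rlang::abort("stride length incompatible with segment lengths",
                 class = "gait_error_infeasible_profile")
  }
  structure(as.list(environment()), class = "gait_profile")
}

# value and time-derivative of a truncated Fourier series in cycle phase
fourier_eval <- function(c_phase, cdot, coef) {
  v <- rep(coef$a0, length(c_phase))
  dv <- numeric(length(c_phase))
  for (k in seq_along(coef$amp)) {
    arg <- 2 * pi * k * c_phase + coef$phase[k]
    v <- v + coef$amp[k] * cos(arg)
    dv <- dv - coef$amp[k] * sin(arg) * 2 * pi * k * cdot
  }
  list(v = v, d = dv)
}

# quintic smoothstep envelope: 0 before a, 1 after b, C2 everywhere (the
# extra continuity keeps segment angular rates kink-free at ramp ends)
smoothstep_eval <- function(t, a, b) {
  x <- pmin(pmax((t - a) / (b - a), 0), 1)
  list(v = x^3 * (10 - 15 * x + 6 * x^2),
       d = 30 * x^2 * (1 - x)^2 / (b - a))
}

# quintic smoothstep and derivatives (zero velocity/acceleration at ends)
quintic <- function(u) {
  list(s = u^3 * (10 - 15 * u + 6 * u^2),
       d1 = 30 * u^2 * (1 - u)^2,
       d2 = 60 * u * (2 * u - 1) * (u - 1))
}

# compact C3 wavelet (1-u^2)^4 on |u|<1 and derivatives; the extra
# smoothness keeps finite-difference checks of the stored rates clean
wavelet <- function(u) {
  inside <- abs(u) < 1
  w <- d1 <- d2 <- numeric(length(u))
  ui <- u[inside]
  w[inside] <- (1 - ui^2)^4
  d1[inside] <- -8 * ui * (1 - ui^2)^3
  d2[inside] <- (1 - ui^2)^2 * (56 * ui^2 - 8)
  list(w = w, d1 = d1, d2 = d2)
}

# rowwise quaternions for single-axis rotations (angle vectors in radians)
qx_rows <- function(a) cbind(cos(a / 2), sin(a / 2), 0, 0)
qy_rows <- function(a) cbind(cos(a / 2), 0, sin(a / 2), 0)

# Rx(theta)^T %*% v rowwise
rxT_rows <- function(theta, V) {
  ct <- cos(theta); st <- sin(theta)
  cbind(V[, 1], ct * V[, 2] + st * V[, 3], -st * V[, 2] + ct * V[, 3])
}

#' Generate ground-truth gait kinematics
#'
#' Produces a kinematically consistent truth set: per-segment orientations
#' and body-frame angular rates (exact analytic derivatives of the
#' orientation waveforms), analytic foot position/velocity/acceleration
#' with exactly stationary mid-stance intervals, heel-strike and toe-off
#' event times, and clinical joint/pelvic angle series (the ankle angle is
#' derived from the shank and foot orientations, closing the chain).
#'
#' @param profile `gait_profile`.
#' @return list of class `synthetic_truth`; see Details in the package
#'   vignette for the field layout.
#' @export
generate_gait_truth <- function(profile = gait_profile()) {
  p <- profile
  T_cyc <- 2 * 60 / p$cadence_spm
  fs <- p$fs
  t_w0 <- p$static_s
  t_w1 <- t_w0 + p$n_cycles * T_cyc
  t_total <- t_w1 + p$static_s
  tt <- seq(0, t_total, by = 1 / fs)
  n <- length(tt)
  g0 <- STANDARD_GRAVITY
  deg <- pi / 180

  phi <- pmin(pmax((tt - t_w0) / T_cyc, 0), p$n_cycles)
  cdot <- ifelse(tt > t_w0 & tt < t_w1, 1 / T_cyc, 0)
  c_l <- phi %% 1
  c_r <- (phi + 0.5) %% 1

  # amplitude envelope: ramps over the first/last walking cycle
  up <- smoothstep_eval(tt, t_w0, t_w0 + T_cyc)
  dn <- smoothstep_eval(tt, t_w1 - T_cyc, t_w1)
  E <- up$v * (1 - dn$v)
  Ed <- up$d * (1 - dn$v) - up$v * dn$d

  env_wave <- function(w) list(v = E * w$v, d = Ed * w$v + E * w$d)

  # ---- pelvis ------------------------------------------------------------
  # tilt oscillates at twice the cycle frequency (one excursion per step)
  tilt2 <- env_wave(fourier_eval((2 * phi) %% 1, 2 * cdot, list(
    a0 = 0, amp = p$pelvis_tilt_amp_deg, phase = pi / 3)))
  rot_w <- env_wave(fourier_eval(c_l, cdot, list(
    a0 = 0, amp = p$pelvis_rot_amp_deg, phase = -pi / 2)))
  tilt <- tilt2$v * deg; tilt_d <- tilt2$d * deg
  rot <- rot_w$v * deg; rot_d <- rot_w$d * deg

  q_pelvis <- quat_multiply_rows(qy_rows(rot), qx_rows(tilt))
  w_pelvis <- cbind(tilt_d, rot_d * cos(tilt), -rot_d * sin(tilt))

  # ---- hips and knees (clinical waveforms, per side) ---------------------
  seg <- list()
  rates <- list()
  seg$pelvis <- q_pelvis
  rates$pelvis <- w_pelvis
  hip <- list(); knee <- list(); raw_hip <- list(); raw_knee <- list()
  for (side in c("l", "r")) {
    cph <- if (side == "l") c_l else c_r
    h <- env_wave(fourier_eval(cph, cdot, p$hip_coef))
    k <- env_wave(fourier_eval(cph, cdot, p$knee_coef))
    hip[[side]] <- h; knee[[side]] <- k
    rh <- -h$v * deg; rhd <- -h$d * deg      # clinical flexion -> raw X
    rk <- k$v * deg; rkd <- k$d * deg
    raw_hip[[side]] <- rh; raw_knee[[side]] <- rk
    q_th <- quat_multiply_rows(q_pelvis, qx_rows(rh))
    w_th <- rxT_rows(rh, w_pelvis)
    w_th[, 1] <- w_th[, 1] + rhd
    q_sh <- quat_multiply_rows(q_th, qx_rows(rk))
    w_sh <- rxT_rows(rk, w_th)
    w_sh[, 1] <- w_sh[, 1] + rkd
    seg[[paste0("thigh_", side)]] <- q_th
    rates[[paste0("thigh_", side)]] <- w_th
    seg[[paste0("shank_", side)]] <- q_sh
    rates[[paste0("shank_", side)]] <- w_sh
  }

  # ---- step timing -------------------------------------------------------
  T_sw <- (1 - p$duty) * T_cyc
  # impact transient half-width: the acceleration lobe spans ~0.76 tau, so
  # 50 ms keeps the heel-strike pulse wider than typical preprocessing
  # median windows while staying well inside the stance guard
  tau <- 0.05
  A_hs <- -p$impact_peak * tau^2 / 8        # heel-strike dip amplitude
  A_to <- +p$impact_peak * tau^2 / 8
  delta_pitch <- 0.15 * T_cyc               # pitch transient half-width, s

  swing_times <- function(side) {
    # (to, hs, advance) for each executed swing; the right foot leads with
    # a half step and every other advance is a full stride
    if (side == "l") {
      to <- t_w0 + (p$duty + (0:(p$n_cycles - 1))) * T_cyc
      adv <- rep(p$stride_m, p$n_cycles)
    } else {
      to <- t_w0 + (p$duty - 0.5 + (0:(p$n_cycles - 1))) * T_cyc
      adv <- c(p$stride_m / 2, rep(p$stride_m, p$n_cycles - 1))
    }
    list(to = to, hs = to + T_sw, advance = adv)
  }
  swings <- list(l = swing_times("l"), r = swing_times("r"))

  # ---- foot orientation --------------------------------------------------
  # the sagittal foot angle is zero at rest and in mid-stance (so foot-flat
  # is exactly quiet) with a plantarflexion excursion around each toe off
  # (local minimum -> upward angular-velocity zero crossing at TO) and a
  # dorsiflexion excursion around each heel strike (local maximum ->
  # downward crossing at HS)
  for (side in c("l", "r")) {
    sw <- swings[[side]]
    v <- numeric(n); dv <- numeric(n)
    for (j in seq_along(sw$to)) {
      wto <- wavelet((tt - sw$to[j]) / delta_pitch)
      whs <- wavelet((tt - sw$hs[j]) / delta_pitch)
      v <- v - p$foot_pitch_deg * wto$w + p$foot_pitch_deg * whs$w
      dv <- dv - p$foot_pitch_deg * wto$d1 / delta_pitch +
        p$foot_pitch_deg * whs$d1 / delta_pitch
    }
    seg[[paste0("foot_", side)]] <- qx_rows(v * deg)
    rates[[paste0("foot_", side)]] <- cbind(dv * deg, 0, 0)
  }

  # ---- foot trajectories -------------------------------------------------
  foot_xyz <- function(side) {
    sw <- swings[[side]]
    x0 <- if (side == "l") -p$step_width_m / 2 else p$step_width_m / 2
    pz <- numeric(n); vz <- numeric(n); az <- numeric(n)
    py <- numeric(n); vy <- numeric(n); ay <- numeric(n)
    base_z <- 0
    for (j in seq_along(sw$to)) {
      idx <- tt >= sw$to[j] & tt <= sw$hs[j]
      u <- (tt[idx] - sw$to[j]) / T_sw
      qs <- quintic(u)
      adv <- sw$advance[j]
      pz[idx] <- base_z + adv * qs$s
      vz[idx] <- adv * qs$d1 / T_sw
      az[idx] <- adv * qs$d2 / T_sw^2
      after <- tt > sw$hs[j]
      base_z <- base_z + adv
      pz[after] <- base_z
      s3 <- sin(pi * u)
      py[idx] <- py[idx] + p$swing_clearance_m * s3^3
      vy[idx] <- vy[idx] + p$swing_clearance_m * 3 * pi *
        s3^2 * cos(pi * u) / T_sw
      ay[idx] <- ay[idx] + p$swing_clearance_m * 3 * pi^2 *
        s3 * (3 * cos(pi * u)^2 - 1) / T_sw^2
      # push-off and impact transients
      for (ev in list(list(tc = sw$to[j], A = A_to),
                      list(tc = sw$hs[j], A = A_hs))) {
        u_w <- (tt - ev$tc) / tau
        wv <- wavelet(u_w)
        py <- py + ev$A * wv$w
        vy <- vy + ev$A * wv$d1 / tau
        ay <- ay + ev$A * wv$d2 / tau^2
      }
    }
    list(pos = cbind(x0, py, pz), vel = cbind(0, vy, vz),
         acc = cbind(0, ay, az), swings = sw)
  }
  foot_l <- foot_xyz("l")
  foot_r <- foot_xyz("r")

  # ---- pelvis and limb sensor positions ---------------------------------
  # the pelvis accelerates to a constant forward speed over the first
  # cycle and decelerates over the last (feet, in contrast, move in
  # bursts), plus small vertical bob (twice per cycle) and lateral sway
  # (once per cycle)
  dist_total <- (sum(foot_l$swings$advance) + sum(foot_r$swings$advance)) / 2
  v_walk <- dist_total / (t_w1 - t_w0 - T_cyc)
  ramp_pos <- function(t_on) {
    # integral of the cubic smoothstep speed ramp starting at t_on
    x <- pmin(pmax((tt - t_on) / T_cyc, 0), 1)
    T_cyc * (x^3 - x^4 / 2) + pmax(tt - t_on - T_cyc, 0)
  }
  pel_z <- v_walk * (ramp_pos(t_w0) - ramp_pos(t_w1 - T_cyc))
  bob <- env_wave(fourier_eval((2 * phi) %% 1, 2 * cdot,
                               list(a0 = 0, amp = 1, phase = pi)))
  sway <- env_wave(fourier_eval(c_l, cdot,
                                list(a0 = 0, amp = 1, phase = pi / 2)))
  p_pelvis <- cbind(p$pelvis_sway_m * sway$v,
                    p$pelvis_height_m + p$pelvis_bob_m * bob$v,
                    pel_z)

  hip_off <- function(side) c(if (side == "l") -0.09 else 0.09, -0.10, 0)
  positions <- list(pelvis = p_pelvis)
  for (side in c("l", "r")) {
    q_th <- seg[[paste0("thigh_", side)]]
    q_sh <- seg[[paste0("shank_", side)]]
    p_hip <- p_pelvis + quat_rotate_rows(
      q_pelvis, matrix(hip_off(side), n, 3, byrow = TRUE))
    p_th_sens <- p_hip + quat_rotate_rows(
      q_th, matrix(c(0, -p$sensor_drop_m, 0), n, 3, byrow = TRUE))
    p_knee <- p_hip + quat_rotate_rows(
      q_th, matrix(c(0, -p$thigh_m, 0), n, 3, byrow = TRUE))
    p_sh_sens <- p_knee + quat_rotate_rows(
      q_sh, matrix(c(0, -p$sensor_drop_m, 0), n, 3, byrow = TRUE))
    positions[[paste0("thigh_", side)]] <- p_th_sens
    positions[[paste0("shank_", side)]] <- p_sh_sens
  }
  positions$foot_l <- foot_l$pos
  positions$foot_r <- foot_r$pos

  # ---- events, foot-flat, contacts --------------------------------------
  events <- dplyr::bind_rows(lapply(c("l", "r"), function(side) {
    sw <- (if (side == "l") foot_l else foot_r)$swings
    side_name <- if (side == "l") "left" else "right"
    dplyr::bind_rows(
      tibble::tibble(time = sw$to, type = "TO", side = side_name),
      tibble::tibble(time = sw$hs, type = "HS", side = side_name)
    )
  })) |> dplyr::arrange(.data$time)

  guard <- delta_pitch + 1 / fs
  foot_flat <- dplyr::bind_rows(lapply(c("l", "r"), function(side) {
    sw <- (if (side == "l") foot_l else foot_r)$swings
    side_name <- if (side == "l") "left" else "right"
    k <- seq_len(length(sw$hs) - 1)
    tibble::tibble(side = side_name,
                   start = sw$hs[k] + guard,
                   end = sw$to[k + 1] - guard)
  }))

  contacts <- dplyr::bind_rows(lapply(c("l", "r"), function(side) {
    f <- if (side == "l") foot_l else foot_r
    side_name <- if (side == "l") "left" else "right"
    idx <- vapply(f$swings$hs, function(h) which.min(abs(tt - h)),
                  integer(1))
    tibble::tibble(time = f$swings$hs, side = side_name,
                   x = f$pos[idx, 1], y = f$pos[idx, 2], z = f$pos[idx, 3])
  }))

  # ---- clinical angle series --------------------------------------------
  ankle <- list()
  for (side in c("l", "r")) {
    q_rel <- quat_multiply_rows(
      quat_conjugate_rows(seg[[paste0("shank_", side)]]),
      seg[[paste0("foot_", side)]])
    ankle[[side]] <- -euler_zyx(q_rel)[, "roll"]
  }
  angles <- dplyr::bind_rows(
    tibble::tibble(time = tt, variable = "hip_l", value = hip$l$v),
    tibble::tibble(time = tt, variable = "hip_r", value = hip$r$v),
    tibble::tibble(time = tt, variable = "knee_l", value = knee$l$v),
    tibble::tibble(time = tt, variable = "knee_r", value = knee$r$v),
    tibble::tibble(time = tt, variable = "ankle_l", value = ankle$l),
    tibble::tibble(time = tt, variable = "ankle_r", value = ankle$r),
    tibble::tibble(time = tt, variable = "pelvic_tilt", value = tilt / deg),
    tibble::tibble(time = tt, variable = "pelvic_rotation", value = rot / deg)
  )

  structure(list(
    time = tt, fs = fs, profile = p,
    t_walk = c(t_w0, t_w1),
    orientations = seg, angular_rates = rates, positions = positions,
    foot = list(left = foot_l[c("pos", "vel", "acc")],
                right = foot_r[c("pos", "vel", "acc")]),
    angles = angles, events = events, foot_flat = foot_flat,
    contacts = contacts
  ), class = "synthetic_truth")
}

#' Measurement noise model for IMU synthesis
#'
#' Defaults: gyroscope white noise 0.005 rad/s, accelerometer 0.2 m/s^2,
#' magnetometer 0.01 (normalized units), small constant per-node biases,
#' 3-degree RMS random sensor mounting misalignment. Identical seeds give
#' bit-identical streams.
#'
#' @param gyro_sigma,accel_sigma,mag_sigma per-sample white noise SDs.
#' @param gyro_bias,accel_bias per-axis bias magnitudes (drawn uniformly in
#'   `+/-` the value per node).
#' @param mount_misalign_deg SD of the random mounting misalignment angle.
#' @param soft_tissue_amp,soft_tissue_freq amplitude (m/s^2) and frequency
#'   (Hz) of a sinusoidal soft-tissue artefact added to thigh and shank
#'   accelerometers (0 disables).
#' @param linear_accel_scale fraction of the sensor's true linear
#'   (translational) acceleration entering the accelerometer model of the
#'   pelvis, thigh and shank nodes, in `[0, 1]`. At 0 those accelerometers
#'   observe the pure gravity reaction — the idealized vector observation
#'   under which the complementary filter's error vector vanishes along the
#'   true trajectory; at 1 the full rigid-body specific force is
#'   synthesized. Foot nodes always carry the full specific force because
#'   trajectory reconstruction integrates it.
#' @param seed RNG seed.
#' @export
noise_model <- function(gyro_sigma = 0.005, accel_sigma = 0.2,
                        mag_sigma = 0.01, gyro_bias = 0.005,
                        accel_bias = 0.05, mount_misalign_deg = 3,
                        soft_tissue_amp = 0, soft_tissue_freq = 8,
                        linear_accel_scale = 0, seed = 1L) {
  stopifnot(all(c(gyro_sigma, accel_sigma, mag_sigma) >= 0),
            linear_accel_scale >= 0, linear_accel_scale <= 1)
  structure(as.list(environment()), class = "noise_model")
}

#' Zero-noise, ideally mounted measurement model
#' @param seed RNG seed (unused when everything is zero, kept for API
#'   symmetry).
#' @export
noise_free <- function(seed = 1L) {
  noise_model(gyro_sigma = 0, accel_sigma = 0, mag_sigma = 0,
              gyro_bias = 0, accel_bias = 0, mount_misalign_deg = 0,
              soft_tissue_amp = 0, linear_accel_scale = 0, seed = seed)
}

NODE_SEGMENTS <- c("pelvis", "thigh_l", "thigh_r", "shank_l", "shank_r",
                   "foot_l", "foot_r")

# second central difference of each column (endpoints replicated)
second_diff_cols <- function(t, P) {
  dt <- t[2] - t[1]
  n <- nrow(P)
  A <- (P[c(3:n, n, n), , drop = FALSE] - 2 * P +
          P[c(1, 1, 1:(n - 2)), , drop = FALSE]) / dt^2
  A[1, ] <- A[3, ]; A[2, ] <- A[3, ]
  A[n, ] <- A[n - 2, ]; A[n - 1, ] <- A[n - 2, ]
  A
}

#' Synthesize seven IMU node streams from ground truth
#'
#' Inverts the measurement model per node: the gyroscope reads the segment
#' body rate expressed in the (possibly misaligned) sensor frame plus bias
#' and noise; the accelerometer reads the sensor-frame specific force
#' (linear acceleration minus gravity); the magnetometer reads the global
#' magnetic reference rotated into the sensor frame. Foot accelerations are
#' analytic; thigh/shank/pelvis sensor accelerations are obtained by
#' differentiating the sensor positions.
#'
#' @param truth `synthetic_truth`.
#' @param noise `noise_model`.
#' @param b_n global magnetic reference direction (unit vector).
#' @return long tibble (`time`, `node`, `gx..gz`, `ax..az`, `mx..mz`) of
#'   class `trial_recording`, with attributes `fs`, `misalignments` (true
#'   per-node mounting quaternions) and `noise`.
#' @export
synthesize_imu <- function(truth, noise = noise_model(),
                           b_n = c(0, -sin(pi / 3), cos(pi / 3))) {
  set.seed(noise$seed)
  tt <- truth$time
  n <- length(tt)
  g0 <- STANDARD_GRAVITY
  b_n <- b_n / sqrt(sum(b_n^2))

  mis <- list()
  out <- vector("list", length(NODE_SEGMENTS))
  for (j in seq_along(NODE_SEGMENTS)) {
    node <- NODE_SEGMENTS[j]
    Q <- truth$orientations[[node]]
    W <- truth$angular_rates[[node]]

    # mounting misalignment: random axis, normal angle
    ang <- stats::rnorm(1, 0, noise$mount_misalign_deg) * pi / 180
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    q_mis <- quat_from_axis_angle(ax, ang)
    mis[[node]] <- q_mis

    # feet always carry the full specific force: trajectory reconstruction
    # integrates it, and during stance the foot is quiet anyway; proximal
    # nodes expose the translational component through linear_accel_scale
    F_glob <- if (node == "foot_l") truth$foot$left$acc
    else if (node == "foot_r") truth$foot$right$acc
    else noise$linear_accel_scale *
      second_diff_cols(tt, truth$positions[[node]])
    F_glob[, 2] <- F_glob[, 2] + g0

    Q_sens <- quat_multiply_rows(Q, matrix(q_mis, n, 4, byrow = TRUE))
    gyro <- quat_rotate_rows_inv(
      matrix(q_mis, n, 4, byrow = TRUE), W)
    accel <- quat_rotate_rows_inv(Q_sens, F_glob)
    mag <- quat_rotate_rows_inv(Q_sens, matrix(b_n, n, 3, byrow = TRUE))

    gb <- stats::runif(3, -noise$gyro_bias, noise$gyro_bias)
    ab <- stats::runif(3, -noise$accel_bias, noise$accel_bias)
    gyro <- sweep(gyro, 2, gb, "+") +
      matrix(stats::rnorm(3 * n, 0, noise$gyro_sigma), n, 3)
    accel <- sweep(accel, 2, ab, "+") +
      matrix(stats::rnorm(3 * n, 0, noise$accel_sigma), n, 3)
    if (noise$soft_tissue_amp > 0 && grepl("thigh|shank", node)) {
      ph <- stats::runif(3, 0, 2 * pi)
      accel <- accel + noise$soft_tissue_amp *
        sin(outer(2 * pi * noise$soft_tissue_freq * tt, c(1, 1, 1)) +
              matrix(ph, n, 3, byrow = TRUE))
    }
    mag <- mag + matrix(stats::rnorm(3 * n, 0, noise$mag_sigma), n, 3)

    out[[j]] <- tibble::tibble(
      time = tt, node = node,
      gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
      ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
      mx = mag[, 1], my = mag[, 2], mz = mag[, 3]
    )
  }
  trial <- dplyr::bind_rows(out)
  class(trial) <- c("trial_recording", class(trial))
  attr(trial, "fs") <- truth$fs
  attr(trial, "misalignments") <- mis
  attr(trial, "noise") <- noise
  trial
}

#' Synthesize a reference (optical-capture-style) angle data set
#'
#' Resamples the true kinematic angle series to a reference rate (default
#' 100 Hz), delays it by a known lag, and adds marker-noise jitter; used to
#' exercise the temporal-alignment and agreement machinery with known
#' ground truth.
#'
#' @param truth `synthetic_truth`.
#' @param marker_noise_deg angle noise SD, degrees.
#' @param lag_s the reference clock offset: the reference reports at time
#'   `t` the true angles of time `t - lag_s`.
#' @param fs_out reference sampling rate, Hz.
#' @param seed RNG seed.
#' @return long tibble `time`, `variable`, `value` (degrees).
#' @export
synthesize_reference <- function(truth, marker_noise_deg = 0.5, lag_s = 0,
                                 fs_out = 100, seed = 1L) {
  if (abs(lag_s) > 2) {
    rlang::abort("lag must be within +/-2 s",
                 class = "gait_error_invalid_argument")
  }
  set.seed(seed)
  grid <- seq(min(truth$time), max(truth$time), by = 1 / fs_out)
  dplyr::bind_rows(lapply(split(truth$angles, truth$angles$variable),
    function(df) {
      v <- stats::approx(df$time, df$value, xout = grid - lag_s,
                         rule = 2)$y
      tibble::tibble(time = grid, variable = df$variable[1],
                     value = v + stats::rnorm(length(grid), 0,
                                              marker_noise_deg))
    }))
}
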