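test_that("profiles validate their feasibility constraints", {
  expect_error(gait_profile(duty = 0.4),
               class = "gait_error_infeasible_profile")
  expect_error(gait_profile(stride_m = 2.5, thigh_m = 0.4, shank_m = 0.4),
               class = "gait_error_infeasible_profile")
})

test_that("step-event construction follows the cadence arithmetic", {
  # 120 steps/min and 15 cycles: 30 heel strikes, 30 toe offs
  truth <- generate_gait_truth(gait_profile(cadence_spm = 120,
                                            n_cycles = 15))
  expect_equal(sum(truth$events$type == "HS"), 30)
  expect_equal(sum(truth$events$type == "TO"), 30)
  # same-side heel strikes are one cycle apart
  hs_l <- sort(truth$events$time[truth$events$type == "HS" &
                                   truth$events$side == "left"])
  expect_equal(unique(round(diff(hs_l), 9)), 1)
})

test_that("stored angular rates are the derivatives of the orientations", {
  truth <- default_truth
  tt <- truth$time
  dt <- tt[2] - tt[1]
  for (nd in names(truth$orientations)) {
    Q <- truth$orientations[[nd]]
    W <- truth$angular_rates[[nd]]
    n <- nrow(Q)
    i <- 3:(n - 2)
    # fifth-order central difference of q, then omega = 2 * vec(q^-1 dq)
    dQ <- (-Q[i + 2, ] + 8 * Q[i + 1, ] - 8 * Q[i - 1, ] + Q[i - 2, ]) /
      (12 * dt)
    prod <- gaitnet:::quat_multiply_rows(
      gaitnet:::quat_conjugate_rows(Q[i, ]), dQ)
    W_fd <- 2 * prod[, 2:4]
    expect_lt(max(abs(W_fd - W[i, ])), 1e-3)
  }
})

test_that("feet are exactly stationary inside foot-flat intervals", {
  truth <- default_truth
  for (side in c("left", "right")) {
    vel <- truth$foot[[side]]$vel
    ff <- truth$foot_flat[truth$foot_flat$side == side, ]
    for (i in seq_len(nrow(ff))) {
      idx <- truth$time >= ff$start[i] & truth$time <= ff$end[i]
      expect_equal(max(abs(vel[idx, ])), 0)
    }
  }
})

test_that("the static measurement model is exact at zero noise", {
  prof <- gait_profile(n_cycles = 2, static_s = 2)
  truth <- generate_gait_truth(prof)
  trial <- synthesize_imu(truth, noise_free())
  static <- trial[trial$time < 1.5, ]
  for (nd in unique(static$node)) {
    s <- static[static$node == nd, ]
    expect_lt(max(abs(c(s$gx, s$gy, s$gz))), 1e-9)
    expect_equal(s$ay, rep(9.80665, nrow(s)), tolerance = 1e-9)
    expect_lt(max(abs(c(s$ax, s$az))), 1e-9)
    b_n <- c(0, -sin(pi / 3), cos(pi / 3))
    expect_equal(unname(as.matrix(s[, c("mx", "my", "mz")])[1, ]), b_n,
                 tolerance = 1e-9)
  }
})

test_that("IMU synthesis is deterministic per seed", {
  prof <- gait_profile(n_cycles = 2, static_s = 1.5)
  truth <- generate_gait_truth(prof)
  a <- synthesize_imu(truth, noise_model(seed = 11))
  b <- synthesize_imu(truth, noise_model(seed = 11))
  c <- synthesize_imu(truth, noise_model(seed = 12))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$gx, c$gx))
})

test_that("a zero-amplitude profile produces a static trial", {
  prof <- gait_profile(
    stride_m = 0, swing_clearance_m = 0, impact_peak = 0,
    foot_pitch_deg = 0, n_cycles = 2, static_s = 1,
    hip_coef = list(a0 = 0, amp = c(0, 0, 0), phase = c(0, 0, 0)),
    knee_coef = list(a0 = 0, amp = c(0, 0, 0), phase = c(0, 0, 0)),
    pelvis_tilt_amp_deg = 0, pelvis_rot_amp_deg = 0,
    pelvis_bob_m = 0, pelvis_sway_m = 0)
  truth <- generate_gait_truth(prof)
  expect_lt(max(abs(truth$angles$value)), 1e-9)
  trial <- synthesize_imu(truth, noise_free())
  # no events are detectable in a static recording
  s <- trial[trial$node == "foot_l", ]
  q <- estimate_orientation(s)
  ev <- detect_events(gaitnet:::vertical_accel(s, q), s$gx, time = s$time)
  expect_equal(nrow(ev), 0)
})

test_that("the synthetic reference reproduces truth and injected lags", {
  truth <- default_truth
  ref <- synthesize_reference(truth, marker_noise_deg = 0, lag_s = 0)
  hip_r <- ref[ref$variable == "hip_l", ]
  hip_t <- truth$angles[truth$angles$variable == "hip_l", ]
  on_grid <- stats::approx(hip_t$time, hip_t$value, xout = hip_r$time)$y
  expect_equal(hip_r$value, on_grid, tolerance = 1e-6)

  # a 0.37 s lag is recovered within one sample by cross-correlation
  ref_lag <- synthesize_reference(truth, marker_noise_deg = 0, lag_s = 0.37)
  tilt_ref <- ref_lag[ref_lag$variable == "pelvic_tilt", ]
  tilt_tru <- truth$angles[truth$angles$variable == "pelvic_tilt", ]
  pair <- align_by_xcorr(
    tibble::tibble(time = tilt_tru$time, value = tilt_tru$value),
    tibble::tibble(time = tilt_ref$time, value = tilt_ref$value))
  expect_lt(abs(pair$lag - 0.37), 0.011)
})
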