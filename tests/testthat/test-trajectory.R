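test_that("ZUPT cancels constant accelerometer bias on a stationary foot", {
  fs <- 200
  tt <- seq(0, 10, by = 1 / fs)
  n <- length(tt)
  stream <- tibble::tibble(
    time = tt, gx = 0, gy = 0, gz = 0,
    ax = 0, ay = 9.80665, az = 0.1,   # 0.1 m/s^2 forward bias
    mx = 0, my = 0, mz = 1)
  orient <- tibble::tibble(time = tt, qw = 1, qx = 0, qy = 0, qz = 0)
  intervals <- tibble::tibble(start = c(2, 5, 8), end = c(2.5, 5.5, 8.5),
                              mid = c(2.25, 5.25, 8.25))
  traj <- reconstruct_trajectory(stream, orient, intervals)
  expect_lt(max(abs(traj$pz)), 1e-3)
  # velocity is exactly zero at every anchor midpoint
  for (m in intervals$mid) {
    i <- which.min(abs(tt - m))
    expect_equal(traj$vz[i], 0, tolerance = 1e-12)
  }
  # without ZUPT the drift grows quadratically: ~ b t^2 / 2
  expect_warning(
    raw <- reconstruct_trajectory(stream, orient,
                                  intervals[0, , drop = FALSE]),
    class = "gait_warning_uncorrected_integration")
  expect_equal(raw$pz[n], 0.1 * 10^2 / 2, tolerance = 0.01)
  expect_false(attr(raw, "zupt_applied"))
})

test_that("simulated strides are recovered within tolerance", {
  truth <- default_truth
  trial <- synthesize_imu(truth, noise_free())
  res <- run_pipeline(trial)
  sl <- res$spatiotemporal$summary$stride_length_m
  truth_sl <- mean(abs(diff(truth$contacts$z[truth$contacts$side == "left"])))
  # left-side strides are all full strides of the profile
  expect_equal(truth_sl, gait_profile()$stride_m)
  left <- res$spatiotemporal$strides
  left <- left$stride_length[left$side == "left"]
  expect_lt(max(abs(left - truth_sl) / truth_sl), 0.05)
  expect_lt(abs(sl - truth_sl) / truth_sl, 0.05)
})

test_that("spatiotemporal arithmetic matches its definitions", {
  mk_traj <- function(contacts) {
    tr <- tibble::tibble(time = 0, vx = 0, vy = 0, vz = 0,
                         px = 0, py = 0, pz = 0)
    class(tr) <- c("foot_trajectory", class(tr))
    attr(tr, "contacts") <- contacts
    attr(tr, "intervals") <- tibble::tibble(start = 0, end = 0, mid = 0)
    attr(tr, "zupt_applied") <- TRUE
    tr
  }
  # 25 contacts alternating over 12 s, walking axis = Z, stride 1.36
  times <- seq(0, 12, length.out = 25)
  sides <- rep(c("left", "right"), length.out = 25)
  z <- 0.68 * (seq_along(times) - 1)
  x <- ifelse(sides == "left", -0.05, 0.05)
  contacts <- tibble::tibble(time = times, side = sides, x = x, y = 0, z = z)
  left <- mk_traj(contacts[contacts$side == "left", ])
  right <- mk_traj(contacts[contacts$side == "right", ])
  events <- tibble::tibble(time = times, type = "HS", side = sides,
                           index = seq_along(times))
  st <- spatiotemporal_params(left, right, events)
  expect_equal(st$summary$cadence_spm, (25 - 1) / 12 * 60)   # 120 steps/min
  expect_equal(st$summary$stride_length_m, 1.36, tolerance = 1e-9)
  expect_equal(st$summary$step_width_m, 0.2, tolerance = 1e-9)

  # velocity: net walking-axis displacement over elapsed time
  expect_equal(st$summary$velocity_ms, (z[25] - z[1]) / 12, tolerance = 1e-9)

  # two contacts 1.36 m apart -> a single stride of that length
  c2 <- tibble::tibble(time = c(0, 1.05), side = "left", x = 0, y = 0,
                       z = c(0, 1.36))
  c3 <- tibble::tibble(time = c(0.5, 1.55), side = "right", x = 0, y = 0,
                       z = c(0.68, 2.04))
  st2 <- spatiotemporal_params(
    mk_traj(c2), mk_traj(c3),
    tibble::tibble(time = c(0, 1.05), type = "HS", side = "left",
                   index = 1:2))
  expect_equal(st2$strides$stride_length[st2$strides$side == "left"], 1.36,
               tolerance = 1e-9)

  expect_error(
    spatiotemporal_params(mk_traj(c2[1, ]), mk_traj(c3), events),
    class = "gait_error_insufficient_strides")
})

test_that("projected stride length never exceeds the Euclidean variant", {
  truth <- default_truth
  trial <- synthesize_imu(truth, noise_model(seed = 4))
  res <- run_pipeline(trial)
  st <- res$spatiotemporal$strides
  expect_true(all(st$stride_length <= st$stride_length_norm + 1e-12))
})

test_that("cadence is consistent with mean cycle duration", {
  truth <- default_truth
  trial <- synthesize_imu(truth, noise_free())
  res <- run_pipeline(trial)
  s <- res$spatiotemporal$summary
  expect_lt(abs(s$cadence_spm - 120 / s$cycle_time_s) / s$cadence_spm, 0.05)
})

test_that("removing ZUPT correction degrades stride accuracy", {
  truth <- default_truth
  trial <- synthesize_imu(truth, noise_model(seed = 6))
  res <- run_pipeline(trial)
  side <- "left"
  nd <- "foot_l"
  s <- trial[trial$node == nd, ]
  b <- estimate_gyro_bias(s[s$time <= 2, ])
  s$gx <- s$gx - b[1]; s$gy <- s$gy - b[2]; s$gz <- s$gz - b[3]
  ev <- res$events[res$events$side == side, ]
  orient <- res$orientations[[nd]]
  flats <- res$foot_flat[[side]]
  with_z <- reconstruct_trajectory(s, orient, flats, events = ev)
  expect_warning(
    without_z <- reconstruct_trajectory(s, orient, flats[0, , drop = FALSE],
                                        events = ev),
    class = "gait_warning_uncorrected_integration")
  err <- function(tr) {
    cc <- attr(tr, "contacts")
    mean(abs(diff(cc$z) - gait_profile()$stride_m))
  }
  expect_lt(err(with_z), err(without_z))
})
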