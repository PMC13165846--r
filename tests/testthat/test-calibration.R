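test_that("gyro bias estimation recovers constant and noisy biases", {
  G <- matrix(rep(c(0.01, -0.02, 0.005), each = 400), ncol = 3)
  colnames(G) <- c("gx", "gy", "gz")
  expect_equal(unname(estimate_gyro_bias(G)), c(0.01, -0.02, 0.005))

  set.seed(123)
  truth <- c(0.003, -0.004, 0.002)
  n <- 2000; sigma <- 0.01
  G <- sweep(matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3), 2, truth, "+")
  colnames(G) <- c("gx", "gy", "gz")
  b <- estimate_gyro_bias(G)
  expect_lt(max(abs(b - truth)), 3 * sigma / sqrt(n))
  # subtracting the estimate zeroes the calibration segment itself
  expect_lt(max(abs(colMeans(sweep(G, 2, b, "-")))), 1e-12)

  spin <- matrix(stats::rnorm(600, 0, 0.5), ncol = 3)
  colnames(spin) <- c("gx", "gy", "gz")
  expect_error(estimate_gyro_bias(spin), class = "gait_error_not_static")
  expect_error(estimate_gyro_bias(G[1:50, ]), class = "gait_error_not_static")
})

six_positions <- function(scale = c(1, 1, 1), bias = c(0, 0, 0),
                          g = 9.80665) {
  A <- matrix(0, 6, 3)
  for (k in 1:3) {
    A[2 * k - 1, k] <- g
    A[2 * k, k] <- -g
  }
  sweep(A %*% diag(scale), 2, bias, "+")
}

test_that("six-position accelerometer calibration inverts its forward model", {
  cal <- calibrate_accel_six_position(six_positions())
  expect_equal(unname(cal$scale), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(cal$bias), c(0, 0, 0), tolerance = 1e-12)

  sc <- c(1.02, 0.98, 1.01); bi <- c(0.1, -0.05, 0.2)
  cal <- calibrate_accel_six_position(six_positions(sc, bi))
  expect_equal(unname(cal$scale), sc, tolerance = 1e-9)
  expect_equal(unname(cal$bias), bi, tolerance = 1e-9)
  # applying the calibration restores the ideal readings
  fixed <- apply_accel_calibration(six_positions(sc, bi), cal)
  expect_equal(fixed, six_positions(), tolerance = 1e-9)

  set.seed(99)
  reps <- replicate(50, {
    noisy <- six_positions(sc, bi) + matrix(stats::rnorm(18, 0, 0.05), 6, 3)
    cal <- calibrate_accel_six_position(noisy)
    c(max(abs(cal$scale - sc)), max(abs(cal$bias - bi)))
  })
  expect_lt(mean(reps[1, ]), 0.01)
  expect_lt(mean(reps[2, ]), 0.05)

  degenerate <- six_positions()
  degenerate[2, ] <- degenerate[1, ]   # two identical positions
  expect_error(calibrate_accel_six_position(degenerate),
               class = "gait_error_degenerate_calibration")
})

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

test_that("ellipsoid magnetometer calibration recovers hard and soft iron", {
  S <- fibonacci_sphere(500)
  cal <- calibrate_mag_ellipsoid(S)
  expect_lt(max(abs(cal$offset)), 1e-6)
  expect_lt(max(abs(cal$correction - diag(3))), 1e-6)

  offset <- c(0.2, -0.1, 0.3)
  soft <- diag(c(1.1, 0.9, 1.05))
  distorted <- sweep(S %*% soft, 2, offset, "+")
  cal <- calibrate_mag_ellipsoid(distorted)
  expect_equal(cal$offset, offset, tolerance = 1e-4)
  expect_equal(cal$correction, solve(soft), tolerance = 1e-4)
  corrected <- apply_mag_calibration(distorted, cal)
  expect_lt(max(abs(sqrt(rowSums(corrected^2)) - 1)), 1e-6)

  set.seed(17)
  noisy <- distorted + matrix(stats::rnorm(1500, 0, 0.005), ncol = 3)
  cal <- calibrate_mag_ellipsoid(noisy)
  norms <- sqrt(rowSums(apply_mag_calibration(noisy, cal)^2))
  expect_lt(stats::sd(norms) / mean(norms), 0.01)

  flat <- cbind(stats::rnorm(100), stats::rnorm(100), 0)
  expect_error(calibrate_mag_ellipsoid(flat),
               class = "gait_error_degenerate_fit")
})

test_that("neutral alignment recovers mounting rotations", {
  expect_equal(
    unclass(compute_neutral_alignment(quat(1, 0, 0, 0), "pelvis")$q),
    c(1, 0, 0, 0))

  # sensor mounted 90 degrees about the segment long (vertical) axis
  q_mount <- quat_from_axis_angle(c(0, 1, 0), pi / 2)
  al <- compute_neutral_alignment(q_mount, "thigh_l")
  expect_lt(quat_angle_deg(apply_alignment(q_mount, al), quat(1, 0, 0, 0)),
            1e-9)
  # alignment composed with its inverse is the identity
  back <- quat_multiply(al$q, quat_conjugate(al$q))
  expect_lt(max(abs(unclass(back) - c(1, 0, 0, 0))), 1e-12)

  wandering <- rbind(c(1, 0, 0, 0),
                     unclass(quat_from_axis_angle(c(1, 0, 0), 0.1)))
  expect_error(compute_neutral_alignment(wandering, "shank_l"),
               class = "gait_error_unstable_neutral")
})

test_that("calibration files round-trip through the key-value format", {
  cals <- list(
    foot_l = list(
      gyro_bias = c(gx = 0.001, gy = -0.002, gz = 0.0005),
      accel = calibrate_accel_six_position(
        six_positions(c(1.02, 0.98, 1.01), c(0.1, -0.05, 0.2))),
      mag = calibrate_mag_ellipsoid(
        sweep(fibonacci_sphere(200) %*% diag(c(1.1, 0.9, 1.05)), 2,
              c(0.2, -0.1, 0.3), "+")),
      alignment = compute_neutral_alignment(
        quat_from_axis_angle(c(0, 1, 0), pi / 4), "foot_l")
    )
  )
  path <- withr::local_tempfile(fileext = ".cfg")
  write_calibration_file(cals, path)
  back <- read_calibration_file(path)
  expect_equal(unname(back$foot_l$gyro_bias),
               unname(cals$foot_l$gyro_bias), tolerance = 1e-10)
  expect_equal(back$foot_l$accel$scale, cals$foot_l$accel$scale,
               tolerance = 1e-10)
  expect_equal(back$foot_l$mag$correction, cals$foot_l$mag$correction,
               tolerance = 1e-10)
  expect_equal(unclass(back$foot_l$alignment$q),
               unclass(cals$foot_l$alignment$q), tolerance = 1e-10)
})
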