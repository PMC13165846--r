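test_that("adaptive proportional gain follows the Gaussian schedule", {
  p <- ncf_params()
  expect_identical(adaptive_kp(p$g, p), 1.8)
  expect_equal(adaptive_kp(p$g + 1, p), 1.8 * exp(-0.5), tolerance = 1e-12)
  expect_equal(adaptive_kp(p$g - 1, p), adaptive_kp(p$g + 1, p))
  devs <- seq(0, 5, by = 0.25)
  gains <- adaptive_kp(p$g + devs, p)
  expect_true(all(diff(gains) < 0))
  expect_true(all(gains > 0 & gains <= p$kp0))
  # strong attenuation at swing-like deviations
  expect_lt(adaptive_kp(p$g + 3, p), 0.02 * p$kp0)
})

test_that("integral gain switches with gait phase", {
  p <- ncf_params()
  expect_identical(select_ki("stance", p), 0.05)
  expect_identical(select_ki("swing", p), 0.005)
  expect_identical(select_ki("uninitialized", p), 0.05)
  expect_error(ncf_params(ki_high = 0.005, ki_low = 0.05),
               class = "gait_error_invalid_argument")
})

test_that("error vector vanishes at truth and matches the matrix oracle", {
  p <- ncf_params()
  set.seed(21)
  for (i in 1:50) {
    q <- random_unit_quat()
    a <- quat_rotate_inv(q, c(0, 1, 0))
    m <- quat_rotate_inv(q, p$b_n)
    expect_lt(max(abs(error_vector(q, a, m, p))), 1e-12)

    # brute-force via explicit rotation matrices
    a2 <- a + stats::rnorm(3, 0, 0.1)
    m2 <- m + stats::rnorm(3, 0, 0.1)
    R <- quat_to_matrix(q)
    ah <- a2 / sqrt(sum(a2^2)); mh <- m2 / sqrt(sum(m2^2))
    vg <- drop(t(R) %*% c(0, 1, 0)); vb <- drop(t(R) %*% p$b_n)
    oracle <- c(ah[2] * vg[3] - ah[3] * vg[2] + mh[2] * vb[3] - mh[3] * vb[2],
                ah[3] * vg[1] - ah[1] * vg[3] + mh[3] * vb[1] - mh[1] * vb[3],
                ah[1] * vg[2] - ah[2] * vg[1] + mh[1] * vb[2] - mh[2] * vb[1])
    expect_lt(max(abs(error_vector(q, a2, m2, p) - oracle)), 1e-12)
  }

  # small tilt error about X with an exactly-consistent magnetometer leaves
  # only the gravity term: |e| ~ sin(delta)
  delta <- 2 * pi / 180
  q_true <- quat(1, 0, 0, 0)
  q_est <- quat_from_axis_angle(c(1, 0, 0), delta)
  a <- quat_rotate_inv(q_true, c(0, 1, 0))
  m_consistent <- quat_rotate_inv(q_est, p$b_n)
  e <- error_vector(q_est, a, m_consistent, p)
  expect_equal(sqrt(sum(e^2)), sin(delta), tolerance = 0.05)

  expect_error(error_vector(quat(1, 0, 0, 0), c(0, 0, 0), c(1, 0, 0), p),
               class = "gait_error_unusable_sample")
})

test_that("a single filter step is stationary at truth and clamps windup", {
  p <- ncf_params()
  st <- ncf_state(q = quat(1, 0, 0, 0))
  st$phase <- "stance"
  a <- c(0, p$g, 0); m <- p$b_n
  for (i in 1:100) st <- ncf_step(st, c(0, 0, 0), a, m, 1 / 200, "stance", p)
  expect_lt(quat_angle_deg(st$q, quat(1, 0, 0, 0)), 1e-9)
  expect_true(all(abs(st$e_int) <= p$e_int_clamp))
  expect_error(ncf_step(st, c(NA, 0, 0), a, m, 1 / 200, "stance", p),
               class = "gait_error_invalid_argument")
})

test_that("the filter converges from a 20-degree initialization error", {
  p <- ncf_params()
  q_true <- quat(1, 0, 0, 0)
  a <- c(0, p$g, 0); m <- p$b_n
  st <- ncf_state(q = quat_from_axis_angle(c(1, 0, 0), 20 * pi / 180))
  for (i in seq_len(5 * 200)) {
    st <- ncf_step(st, c(0, 0, 0), a, m, 1 / 200, "stance", p)
  }
  expect_lt(quat_angle_deg(st$q, q_true), 0.5)
})

test_that("batch estimation tracks static and constant-rate streams", {
  p <- ncf_params()
  fs <- 200
  tt <- seq(0, 5, by = 1 / fs)
  n <- length(tt)
  mk_stream <- function(Q, W) {
    A <- gaitnet:::quat_rotate_rows_inv(Q, matrix(c(0, p$g, 0), n, 3,
                                                  byrow = TRUE))
    M <- gaitnet:::quat_rotate_rows_inv(Q, matrix(p$b_n, n, 3, byrow = TRUE))
    tibble::tibble(time = tt, gx = W[, 1], gy = W[, 2], gz = W[, 3],
                   ax = A[, 1], ay = A[, 2], az = A[, 3],
                   mx = M[, 1], my = M[, 2], mz = M[, 3])
  }
  # static stream held at a non-trivial orientation
  q0 <- quat_from_euler_zyx(25, 10, -15)
  Q <- matrix(q0, n, 4, byrow = TRUE)
  est <- estimate_orientation(mk_stream(Q, matrix(0, n, 3)), params = p)
  err <- gaitnet:::quat_angle_rows_deg(as.matrix(est[, 2:5]), Q)
  expect_lt(max(err), 1e-6)

  # rotation rate ramping smoothly to 60 deg/s after one static second,
  # vs the closed-form integral of the rate profile
  A <- 60 * pi / 180
  x <- pmin(pmax(tt - 1, 0), 1)
  omega <- A * x^2 * (3 - 2 * x)
  ang <- A * (x^3 - x^4 / 2) + A * pmax(tt - 2, 0)
  Q <- gaitnet:::qx_rows(ang)
  est <- estimate_orientation(mk_stream(Q, cbind(omega, 0, 0)), params = p)
  err <- gaitnet:::quat_angle_rows_deg(as.matrix(est[, 2:5]), Q)
  expect_lt(max(err), 0.1)

  expect_error(estimate_orientation(mk_stream(Q, cbind(omega, 0, 0))[1, ]),
               class = "gait_error_insufficient_data")
})
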