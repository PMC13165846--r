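mk_orient <- function(Q, tt = seq_len(nrow(Q)) / 200) {
  tibble::tibble(time = tt, qw = Q[, 1], qx = Q[, 2], qy = Q[, 3],
                 qz = Q[, 4])
}

test_that("joint angles are zero for coincident segments and recover pure
           mediolateral rotations", {
  n <- 50
  Q <- matrix(rep(unclass(quat_from_euler_zyx(10, 5, 20)), each = n), n, 4)
  ja <- joint_angle_series(mk_orient(Q), mk_orient(Q), joint = "knee")
  expect_lt(max(abs(ja$sagittal)), 1e-9)
  expect_lt(max(abs(ja$frontal)), 1e-9)
  expect_lt(max(abs(ja$transverse)), 1e-9)

  # distal rotated 30 degrees about the mediolateral axis (knee sign: +1)
  Qd <- gaitnet:::quat_multiply_rows(
    Q, matrix(quat_from_axis_angle(c(1, 0, 0), 30 * pi / 180), n, 4,
              byrow = TRUE))
  ja <- joint_angle_series(mk_orient(Q), mk_orient(Qd), joint = "knee")
  expect_equal(ja$sagittal, rep(30, n), tolerance = 1e-9)
  expect_lt(max(abs(ja$frontal)), 1e-9)
  expect_lt(max(abs(ja$transverse)), 1e-9)
})

test_that("swapping proximal and distal negates small sagittal angles", {
  n <- 20
  set.seed(8)
  for (ang in c(-30, -10, 5, 25)) {
    Qp <- matrix(rep(unclass(random_unit_quat()), each = n), n, 4)
    Qd <- gaitnet:::quat_multiply_rows(
      Qp, matrix(quat_from_axis_angle(c(1, 0, 0), ang * pi / 180), n, 4,
                 byrow = TRUE))
    fwd <- joint_angle_series(mk_orient(Qp), mk_orient(Qd), joint = "knee")
    rev <- joint_angle_series(mk_orient(Qd), mk_orient(Qp), joint = "knee")
    expect_equal(fwd$sagittal, -rev$sagittal, tolerance = 1e-9)
  }
})

test_that("pelvic angles pick the sagittal and transverse components", {
  n <- 30
  Q <- matrix(rep(unclass(quat_from_axis_angle(c(0, 1, 0), 10 * pi / 180)),
                  each = n), n, 4)
  pel <- pelvic_angle_series(mk_orient(Q))
  expect_equal(pel$rotation, rep(10, n), tolerance = 1e-9)
  expect_lt(max(abs(pel$tilt)), 1e-9)

  Qt <- matrix(rep(unclass(quat_from_axis_angle(c(1, 0, 0), 7 * pi / 180)),
                   each = n), n, 4)
  pel <- pelvic_angle_series(mk_orient(Qt))
  expect_equal(pel$tilt, rep(7, n), tolerance = 1e-9)
  expect_lt(max(abs(pel$rotation)), 1e-9)
})

test_that("the simulated chain is recovered joint by joint", {
  truth <- default_truth
  trial <- synthesize_imu(truth, noise_free())
  res <- run_pipeline(trial)
  rmse <- angle_rmse(res, truth)
  expect_lt(rmse[["knee_l"]], 1)
  expect_lt(rmse[["hip_r"]], 1)
  expect_lt(rmse[["ankle_l"]], 1)
  expect_lt(rmse[["pelvic_tilt"]], 1)
  expect_lt(rmse[["pelvic_rotation"]], 1)
})

test_that("chain consistency: composed relative rotations reproduce the foot", {
  truth <- default_truth
  q_rel <- function(a, b) {
    gaitnet:::quat_multiply_rows(gaitnet:::quat_conjugate_rows(a), b)
  }
  o <- truth$orientations
  chain <- gaitnet:::quat_multiply_rows(
    o$pelvis,
    gaitnet:::quat_multiply_rows(
      q_rel(o$pelvis, o$thigh_l),
      gaitnet:::quat_multiply_rows(q_rel(o$thigh_l, o$shank_l),
                                   q_rel(o$shank_l, o$foot_l))))
  expect_lt(max(gaitnet:::quat_angle_rows_deg(chain, o$foot_l)), 1e-9)
})

test_that("cycle ROM equals peak-to-peak amplitude over whole cycles", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  A <- 17
  ang <- A * sin(2 * pi * 1 * tt)
  cycles <- tibble::tibble(side = "left", start = 0:8, to = 0:8 + 0.6,
                           end = 1:9, duration = 1, stable = TRUE)
  r <- cycle_rom(tt, ang, cycles)
  expect_equal(r$per_cycle$rom, rep(2 * A, 9), tolerance = 1e-3)
  expect_equal(r$trial_mean, mean(r$per_cycle$rom))

  cycles$stable <- FALSE
  expect_error(cycle_rom(tt, ang, cycles),
               class = "gait_error_insufficient_cycles")
})

test_that("simulated hip ROM is recovered within a degree", {
  truth <- default_truth
  trial <- synthesize_imu(truth, noise_free())
  res <- run_pipeline(trial)
  cyc <- res$cycles[res$cycles$side == "left" & res$cycles$stable, ]
  # restrict to steady cycles (envelope fully on)
  steady <- cyc[cyc$start > 4 & cyc$end < 14, ]
  tru <- truth$angles[truth$angles$variable == "hip_l", ]
  est <- res$angles[res$angles$variable == "hip_l", ]
  rom_t <- cycle_rom(tru$time, tru$value, steady)$trial_mean
  rom_e <- cycle_rom(est$time, est$value, steady)$trial_mean
  expect_lt(abs(rom_t - rom_e), 1)
})
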