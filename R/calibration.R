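#' Sensor calibration
#'
#' Per-node sensor-level calibration performed before each trial: gyroscope
#' zero-bias estimation from a static segment, classic six-position
#' accelerometer calibration (per-axis scale and bias), ellipsoid-based
#' magnetometer calibration compensating hard- and soft-iron distortion, and
#' sensor-to-segment alignment from the neutral standing posture.
#'
#' @name calibration
NULL

STANDARD_GRAVITY <- 9.80665

#' Estimate the gyroscope zero bias from a static segment
#'
#' The bias is the per-axis mean of the gyroscope signal over a segment in
#' which the node is static. A segment qualifies as static when the norm of
#' the (bias-removed) angular rate stays small; here the per-axis standard
#' deviation must stay below `static_sd_max` and at least one second of
#' samples must be supplied.
#'
#' @param static_gyro data frame or matrix with columns gx, gy, gz (rad/s).
#' @param fs sampling frequency, Hz.
#' @param static_sd_max maximum per-axis standard deviation (rad/s) for the
#'   segment to count as static.
#' @return named numeric vector `c(gx, gy, gz)` — the gyro bias in rad/s.
#' @export
estimate_gyro_bias <- function(static_gyro, fs = 200, static_sd_max = 0.02) {
  G <- as.matrix(static_gyro[, c("gx", "gy", "gz"), drop = FALSE])
  if (nrow(G) < fs) {
    rlang::abort("need at least one second of static samples",
                 class = "gait_error_not_static")
  }
  sds <- apply(G, 2, stats::sd)
  if (any(sds > static_sd_max)) {
    rlang::abort(
      sprintf("segment not static: per-axis sd up to %.4f rad/s", max(sds)),
      class = "gait_error_not_static"
    )
  }
  b <- colMeans(G)
  names(b) <- c("gx", "gy", "gz")
  b
}

#' Six-position accelerometer calibration
#'
#' Identifies per-axis scale factors and biases from the mean readings of
#' six static positions with gravity aligned +/- each sensor axis. The model
#' is `a_true = (a_meas - bias) / scale` per axis, with the true reading
#' equal to +/-g on the aligned axis and 0 elsewhere. With the six classic
#' positions the least-squares solution reduces to the closed form
#' `scale = (a_plus - a_minus) / (2 g)`, `bias = (a_plus + a_minus) / 2`.
#'
#' @param six_static_means 6 x 3 matrix (or data frame) of mean accelerometer
#'   readings, m/s^2. Rows ordered +X, -X, +Y, -Y, +Z, -Z.
#' @param g gravity magnitude, m/s^2.
#' @return list with `scale` and `bias` (named length-3 vectors) of class
#'   `accel_calibration`.
#' @export
calibrate_accel_six_position <- function(six_static_means,
                                         g = STANDARD_GRAVITY) {
  A <- as.matrix(six_static_means)
  if (nrow(A) != 6 || ncol(A) != 3) {
    rlang::abort("six_static_means must be 6 x 3",
                 class = "gait_error_invalid_argument")
  }
  if (any(!stats::complete.cases(A)) || !all(is.finite(A))) {
    rlang::abort("six_static_means must be finite",
                 class = "gait_error_invalid_argument")
  }
  # rows (2k-1, 2k) are +/- gravity along axis k; regressor values are
  # (+g, -g, 0, 0, 0, 0) up to row order, so the per-axis least squares has
  # the closed form slope = (plus - minus)/(2g), intercept = column mean
  scale <- numeric(3); bias <- numeric(3)
  for (k in 1:3) {
    plus <- A[2 * k - 1, k]
    minus <- A[2 * k, k]
    scale[k] <- (plus - minus) / (2 * g)
    bias[k] <- mean(A[, k])
  }
  if (any(scale < 0.5 | scale > 2)) {
    rlang::abort("degenerate six-position input: scale outside (0.5, 2)",
                 class = "gait_error_degenerate_calibration")
  }
  structure(list(scale = stats::setNames(scale, c("x", "y", "z")),
                 bias = stats::setNames(bias, c("x", "y", "z"))),
            class = "accel_calibration")
}

#' Apply an accelerometer calibration
#' @param accel n x 3 matrix of raw readings (m/s^2).
#' @param cal `accel_calibration` object.
#' @export
apply_accel_calibration <- function(accel, cal) {
  A <- as.matrix(accel)
  sweep(sweep(A, 2, cal$bias, "-"), 2, cal$scale, "/")
}

#' Ellipsoid-based magnetometer calibration
#'
#' Fits the general quadric `x'Ax + b'x + c = 0` to the raw magnetometer
#' samples by linear least squares, then derives the hard-iron offset (the
#' ellipsoid centre) and a symmetric soft-iron correction matrix (inverse
#' symmetric square root of the shape matrix) that maps corrected samples to
#' the unit sphere.
#'
#' @param samples n x 3 matrix or data frame of raw magnetometer readings
#'   spanning a wide range of orientations; n >= 9.
#' @return list with `offset` (length 3) and `correction` (3 x 3 symmetric
#'   positive-definite), class `mag_calibration`. Corrected readings are
#'   `correction %*% (m - offset)`.
#' @export
calibrate_mag_ellipsoid <- function(samples) {
  M <- as.matrix(samples)
  if (nrow(M) < 9) {
    rlang::abort("ellipsoid fit needs at least 9 samples",
                 class = "gait_error_degenerate_fit")
  }
  x <- M[, 1]; y <- M[, 2]; z <- M[, 3]
  # design for x^2, y^2, z^2, xy, xz, yz, x, y, z ~ 1
  D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
  fit <- tryCatch(qr.solve(crossprod(D), crossprod(D, rep(1, nrow(M)))),
                  error = function(e) NULL)
  if (is.null(fit) || qr(D)$rank < 9) {
    rlang::abort("degenerate sample distribution for ellipsoid fit",
                 class = "gait_error_degenerate_fit")
  }
  v <- drop(fit)
  A <- matrix(c(v[1], v[4] / 2, v[5] / 2,
                v[4] / 2, v[2], v[6] / 2,
                v[5] / 2, v[6] / 2, v[3]), 3, 3)
  bvec <- v[7:9]
  eA <- eigen(A, symmetric = TRUE)
  if (any(eA$values <= 0)) {
    rlang::abort("fitted quadric is not an ellipsoid",
                 class = "gait_error_degenerate_fit")
  }
  centre <- -0.5 * solve(A, bvec)
  # x'Ax + b'x = 1  =>  (x-c)'A(x-c) = 1 + c'Ac
  r2 <- 1 + drop(t(centre) %*% A %*% centre)
  if (r2 <= 0) {
    rlang::abort("fitted quadric is not an ellipsoid",
                 class = "gait_error_degenerate_fit")
  }
  S <- A / r2                                 # (x-c)' S (x-c) = 1
  eS <- eigen(S, symmetric = TRUE)
  W <- eS$vectors %*% diag(sqrt(eS$values)) %*% t(eS$vectors)
  structure(list(offset = drop(centre), correction = W),
            class = "mag_calibration")
}

#' Apply a magnetometer calibration
#' @param mag n x 3 matrix of raw readings.
#' @param cal `mag_calibration` object.
#' @return n x 3 matrix of corrected readings lying near the unit sphere.
#' @export
apply_mag_calibration <- function(mag, cal) {
  M <- as.matrix(mag)
  t(cal$correction %*% (t(M) - cal$offset))
}

#' Sensor-to-segment alignment from the neutral standing posture
#'
#' With the anatomical neutral defined as every segment frame coincident
#' with the global frame during quiet standing, the alignment quaternion is
#' the inverse of the converged sensor orientation captured in that posture:
#' composing the sensor orientation with the alignment yields the segment
#' orientation, which is the identity at neutral.
#'
#' @param q_sensor_static unit quaternion of the sensor at neutral standing
#'   (converged orientation filter output), or an n x 4 matrix of the final
#'   static orientations, in which case convergence is checked.
#' @param segment placement label (e.g. "foot_l").
#' @param max_drift_deg maximum mean-orientation change across the static
#'   window for the capture to count as converged (degrees).
#' @return list (`segment_alignment`) with fields `q` (unit quaternion,
#'   sensor-to-segment correction) and `segment`.
#' @export
compute_neutral_alignment <- function(q_sensor_static, segment,
                                      max_drift_deg = 0.5) {
  if (is.matrix(q_sensor_static)) {
    Q <- q_sensor_static
    # drift between the mean orientations of the first and last quarter of
    # the window, so sample-level jitter does not masquerade as drift
    k <- max(1, floor(nrow(Q) / 4))
    q_a <- quat_normalize(colMeans(Q[seq_len(k), , drop = FALSE]))
    q_b <- quat_normalize(colMeans(Q[(nrow(Q) - k + 1):nrow(Q), ,
                                     drop = FALSE]))
    drift <- quat_angle_deg(q_a, q_b)
    if (drift > max_drift_deg) {
      rlang::abort(
        sprintf("static capture not converged: %.3f deg drift", drift),
        class = "gait_error_unstable_neutral"
      )
    }
    q <- quat_normalize(colMeans(Q))
  } else {
    q <- quat_normalize(q_sensor_static)
  }
  structure(list(q = quat_canonical(quat_conjugate(q)), segment = segment),
            class = "segment_alignment")
}

#' Apply a segment alignment to a sensor orientation series
#' @param Q n x 4 matrix of sensor orientations (or a single quaternion).
#' @param alignment `segment_alignment` object.
#' @return segment orientation(s), same shape as `Q`.
#' @export
apply_alignment <- function(Q, alignment) {
  if (is.matrix(Q)) {
    quat_multiply_rows(Q, matrix(alignment$q, nrow(Q), 4, byrow = TRUE))
  } else {
    quat_multiply(Q, alignment$q)
  }
}

#' Write / read node calibrations as a human-readable config file
#'
#' One block per node, `key = value` lines, vectors comma-separated. This is
#' the calibration artefact consumed by the pipeline CLI.
#'
#' @param calibrations named list (per node) of lists with any of
#'   `gyro_bias`, `accel` (`accel_calibration`), `mag` (`mag_calibration`),
#'   `alignment` (`segment_alignment`).
#' @param path file path.
#' @export
write_calibration_file <- function(calibrations, path) {
  fmt <- function(x) paste(formatC(x, format = "g", digits = 12), collapse = ", ")
  lines <- character(0)
  for (node in names(calibrations)) {
    cal <- calibrations[[node]]
    lines <- c(lines, sprintf("[%s]", node))
    if (!is.null(cal$gyro_bias)) {
      lines <- c(lines, paste("gyro_bias =", fmt(cal$gyro_bias)))
    }
    if (!is.null(cal$accel)) {
      lines <- c(lines, paste("accel_scale =", fmt(cal$accel$scale)),
                 paste("accel_bias =", fmt(cal$accel$bias)))
    }
    if (!is.null(cal$mag)) {
      lines <- c(lines, paste("mag_offset =", fmt(cal$mag$offset)),
                 paste("mag_correction =", fmt(as.vector(cal$mag$correction))))
    }
    if (!is.null(cal$alignment)) {
      lines <- c(lines, paste("alignment_quat =", fmt(cal$alignment$q)))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration_file
#' @export
read_calibration_file <- function(path) {
  lines <- readLines(path)
  out <- list()
  node <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      node <- gsub("^\\[|\\]$", "", ln)
      out[[node]] <- list()
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- as.numeric(trimws(strsplit(kv[2], ",")[[1]]))
    out[[node]][[key]] <- val
  }
  lapply(out, function(cal) {
    res <- list()
    if (!is.null(cal$gyro_bias)) {
      res$gyro_bias <- stats::setNames(cal$gyro_bias, c("gx", "gy", "gz"))
    }
    if (!is.null(cal$accel_scale)) {
      res$accel <- structure(
        list(scale = stats::setNames(cal$accel_scale, c("x", "y", "z")),
             bias = stats::setNames(cal$accel_bias, c("x", "y", "z"))),
        class = "accel_calibration")
    }
    if (!is.null(cal$mag_offset)) {
      res$mag <- structure(
        list(offset = cal$mag_offset,
             correction = matrix(cal$mag_correction, 3, 3)),
        class = "mag_calibration")
    }
    if (!is.null(cal$alignment_quat)) {
      res$alignment <- structure(
        list(q = structure(cal$alignment_quat, class = "gait_quat"),
             segment = NA_character_),
        class = "segment_alignment")
    }
    res
  })
}
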