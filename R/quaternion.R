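#' Quaternion algebra for rigid-body orientation
#'
#' Orientations are unit quaternions in Hamilton convention, stored
#' scalar-first as numeric vectors `c(w, x, y, z)`. A quaternion encodes the
#' rotation from the sensor (body) frame to the global frame:
#' `v_global = R(q) %*% v_sensor`. Reference vectors known in the global
#' frame are projected into the sensor frame with the inverse rotation.
#'
#' The global frame is right-handed with X mediolateral (right-positive),
#' Y vertical (up-positive) and Z anteroposterior (forward-positive), so
#' sagittal-plane rotation is about X and transverse-plane rotation about Y.
#'
#' `q` and `-q` encode the same rotation; the canonical representative has
#' `w >= 0`.
#'
#' @param w,x,y,z quaternion components (scalar first).
#' @return A numeric vector of length 4 with class `gait_quat`.
#' @examples
#' q <- quat(1, 0, 0, 0)
#' quat_multiply(q, q)
#' @export
quat <- function(w, x, y, z) {
  q <- c(w, x, y, z)
  if (!all(is.finite(q))) {
    rlang::abort("quaternion components must be finite",
                 class = "gait_error_invalid_argument")
  }
  structure(q, class = "gait_quat")
}

#' @export
print.gait_quat <- function(x, ...) {
  cat(sprintf("<quat w=%.6g x=%.6g y=%.6g z=%.6g>\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

quat_identity <- function() quat(1, 0, 0, 0)

#' Normalize a quaternion to unit length
#'
#' @param q quaternion (length-4 numeric, scalar first).
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n == 0) {
    rlang::abort("cannot normalize a zero or non-finite quaternion",
                 class = "gait_error_invalid_argument")
  }
  structure(q / n, class = "gait_quat")
}

#' Canonical sign representative (scalar part non-negative)
#' @param q quaternion.
#' @export
quat_canonical <- function(q) {
  if (q[1] < 0) q <- -q
  structure(q, class = "gait_quat")
}

#' Quaternion conjugate / inverse of a unit quaternion
#' @param q unit quaternion.
#' @export
quat_conjugate <- function(q) {
  structure(c(q[1], -q[2], -q[3], -q[4]), class = "gait_quat")
}

#' Hamilton product of two quaternions
#'
#' Composition follows the sensor-to-global convention: if `a` rotates frame
#' B to frame C and `b` rotates A to B, then `quat_multiply(a, b)` rotates A
#' to C (matrix order `R(a) %*% R(b)`).
#'
#' @param a,b quaternions (scalar-first, length-4 numeric).
#' @export
quat_multiply <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    rlang::abort("quaternion product requires finite inputs",
                 class = "gait_error_invalid_argument")
  }
  structure(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ), class = "gait_quat")
}

#' Rotation matrix of a unit quaternion
#'
#' @param q unit quaternion (norm within 1e-6 of 1).
#' @return 3x3 orthonormal matrix with determinant +1 mapping sensor-frame
#'   vectors to the global frame.
#' @export
quat_to_matrix <- function(q) {
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-6) {
    rlang::abort("quat_to_matrix requires a unit quaternion",
                 class = "gait_error_invalid_argument")
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix (Shepperd's method)
#' @param R 3x3 rotation matrix.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_canonical(quat_normalize(q))
}

#' Rotate a 3-vector by a unit quaternion (sensor frame to global frame)
#' @param q unit quaternion.
#' @param v numeric length-3 vector.
#' @export
quat_rotate <- function(q, v) {
  # q * (0, v) * q^-1 expanded; cheaper than building the matrix
  w <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  tx <- 2 * (qy * v[3] - qz * v[2])
  ty <- 2 * (qz * v[1] - qx * v[3])
  tz <- 2 * (qx * v[2] - qy * v[1])
  c(v[1] + w * tx + qy * tz - qz * ty,
    v[2] + w * ty + qz * tx - qx * tz,
    v[3] + w * tz + qx * ty - qy * tx)
}

#' Rotate a vector into the sensor frame (inverse rotation)
#' @inheritParams quat_rotate
#' @export
quat_rotate_inv <- function(q, v) {
  quat_rotate(quat_conjugate(q), v)
}

#' Unit quaternion from an axis-angle rotation
#' @param axis length-3 axis (need not be unit).
#' @param angle_rad rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle_rad) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(quat_identity())
  axis <- axis / n
  structure(c(cos(angle_rad / 2), sin(angle_rad / 2) * axis),
            class = "gait_quat")
}

#' First-order quaternion integration of a body angular rate
#'
#' Advances the orientation by one sampling step of the quaternion
#' differential equation `dq/dt = q/2 * (0, omega)` using a first-order
#' update followed by renormalization. At 200 Hz sampling the per-step
#' error is second order in `dt` and negligible against sensor noise.
#'
#' @param q unit quaternion (sensor to global).
#' @param omega body angular rate, rad/s, length 3.
#' @param dt time step in seconds, > 0.
#' @return unit quaternion.
#' @export
integrate_quat <- function(q, omega, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    rlang::abort("dt must be a positive finite scalar",
                 class = "gait_error_invalid_argument")
  }
  if (!all(is.finite(omega))) {
    rlang::abort("angular rate must be finite",
                 class = "gait_error_invalid_argument")
  }
  dq <- quat_multiply(q, c(0, omega))
  quat_normalize(q + 0.5 * dt * unclass(dq))
}

#' Z-Y-X Euler decomposition of a unit quaternion
#'
#' Decomposes `R(q) = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)` and returns the
#' angles in degrees. Under the package frame convention the X (roll) angle
#' is the sagittal-plane component, the Y (pitch) angle the transverse-plane
#' component and the Z (yaw) angle the frontal-plane component.
#'
#' The decomposition is singular when pitch approaches +/-90 degrees; inputs
#' within 0.5 degrees of the singularity raise a degenerate-orientation
#' error carrying the offending sample index (for series input).
#'
#' @param q unit quaternion, or an n x 4 matrix of unit quaternions
#'   (rows scalar-first).
#' @return For a single quaternion, a named numeric vector
#'   `c(yaw, pitch, roll)` in degrees; for a matrix, an n x 3 matrix with
#'   those columns.
#' @export
euler_zyx <- function(q) {
  single <- !is.matrix(q)
  Q <- if (single) matrix(q, nrow = 1) else q
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  sp <- 2 * (w * y - z * x)
  bad <- which(abs(sp) > sin((90 - 0.5) * pi / 180))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("pitch within 0.5 degrees of +/-90 at sample %d", bad[1]),
      class = "gait_error_degenerate_orientation",
      sample_index = bad[1]
    )
  }
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  pitch <- asin(pmin(1, pmax(-1, sp)))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  out <- cbind(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
  if (single) out[1, ] else out
}

#' Unit quaternion from Z-Y-X Euler angles in degrees
#' @param yaw,pitch,roll angles in degrees about the global Z, Y and X axes
#'   applied in that order.
#' @export
quat_from_euler_zyx <- function(yaw, pitch, roll) {
  hz <- yaw * pi / 360; hy <- pitch * pi / 360; hx <- roll * pi / 360
  qz <- c(cos(hz), 0, 0, sin(hz))
  qy <- c(cos(hy), 0, sin(hy), 0)
  qx <- c(cos(hx), sin(hx), 0, 0)
  quat_multiply(quat_multiply(qz, qy), qx)
}

#' Rotation angle between two unit quaternions, degrees
#'
#' Uses the chord length between the (sign-matched) quaternions,
#' `theta = 4 asin(||qa -/+ qb|| / 2)`, which keeps full precision for
#' small angles where the dot-product/acos form loses half the digits.
#'
#' @param qa,qb unit quaternions.
#' @export
quat_angle_deg <- function(qa, qb) {
  d2m <- sum((qa - qb)^2)
  d2p <- sum((qa + qb)^2)
  4 * asin(pmin(1, sqrt(pmin(d2m, d2p)) / 2)) * 180 / pi
}

# ---- internal vectorized helpers on n x 4 quaternion matrices -------------

# rotate rows of the n x 3 matrix V by the rows of Q (sensor -> global)
quat_rotate_rows <- function(Q, V) {
  w <- Q[, 1]; qx <- Q[, 2]; qy <- Q[, 3]; qz <- Q[, 4]
  vx <- V[, 1]; vy <- V[, 2]; vz <- V[, 3]
  tx <- 2 * (qy * vz - qz * vy)
  ty <- 2 * (qz * vx - qx * vz)
  tz <- 2 * (qx * vy - qy * vx)
  cbind(vx + w * tx + qy * tz - qz * ty,
        vy + w * ty + qz * tx - qx * tz,
        vz + w * tz + qx * ty - qy * tx)
}

quat_rotate_rows_inv <- function(Q, V) {
  quat_rotate_rows(cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4]), V)
}

# row-wise Hamilton product of n x 4 matrices (or one row recycled)
quat_multiply_rows <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, nrow = nrow(B), ncol = 4, byrow = TRUE)
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(A), ncol = 4, byrow = TRUE)
  aw <- A[, 1]; ax <- A[, 2]; ay <- A[, 3]; az <- A[, 4]
  bw <- B[, 1]; bx <- B[, 2]; by <- B[, 3]; bz <- B[, 4]
  cbind(aw * bw - ax * bx - ay * by - az * bz,
        aw * bx + ax * bw + ay * bz - az * by,
        aw * by - ax * bz + ay * bw + az * bx,
        aw * bz + ax * by - ay * bx + az * bw)
}

quat_conjugate_rows <- function(Q) {
  cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
}

# angle (deg) between row-wise quaternion series (chord form, see
# quat_angle_deg)
quat_angle_rows_deg <- function(A, B) {
  d2 <- pmin(rowSums((A - B)^2), rowSums((A + B)^2))
  4 * asin(pmin(1, sqrt(d2) / 2)) * 180 / pi
}
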