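#' Joint and pelvic angles from segment orientations
#'
#' Joint rotation is the orientation of the distal segment expressed
#' relative to the proximal segment, `q_joint = q_prox^-1 (x) q_dist`,
#' decomposed in a Z-Y-X Euler sequence. Under the package frame convention
#' the X (last) component is the sagittal-plane angle, the Y component the
#' transverse-plane angle and the Z component the frontal-plane angle.
#'
#' Clinical signs: positive hip and knee angles indicate flexion, positive
#' ankle angles dorsiflexion, positive pelvic tilt anterior tilt. With the
#' mediolateral axis pointing right, hip flexion and ankle dorsiflexion are
#' negative raw X rotations (sign -1) while knee flexion is positive
#' (sign +1); these per-joint signs are applied internally.
#'
#' @name kinematics
NULL

JOINT_SAGITTAL_SIGN <- c(hip = -1, knee = 1, ankle = -1)

# unwrap jumps > 180 deg in a degree series
unwrap_deg <- function(x) {
  d <- diff(x)
  steps <- cumsum(c(0, round(d / 360) * -360))
  x + steps
}

#' Joint angle series from proximal and distal orientation series
#'
#' @param q_prox,q_dist orientation tibbles ([estimate_orientation()]) on a
#'   common time base (sensor orientations).
#' @param alignment_prox,alignment_dist `segment_alignment` objects from
#'   neutral calibration; pass `NULL` when the inputs are already segment
#'   orientations.
#' @param joint "hip", "knee" or "ankle" (selects the clinical sagittal
#'   sign).
#' @param side "left"/"right" label.
#' @return tibble with columns `time`, `joint`, `side`, `sagittal`,
#'   `frontal`, `transverse` (degrees). The sagittal series is unwrapped to
#'   be continuous.
#' @export
joint_angle_series <- function(q_prox, q_dist, alignment_prox = NULL,
                               alignment_dist = NULL,
                               joint = c("hip", "knee", "ankle"),
                               side = "left") {
  joint <- match.arg(joint)
  Qp <- cbind(q_prox$qw, q_prox$qx, q_prox$qy, q_prox$qz)
  Qd <- cbind(q_dist$qw, q_dist$qx, q_dist$qy, q_dist$qz)
  if (nrow(Qp) != nrow(Qd)) {
    rlang::abort("proximal and distal series must share a time base",
                 class = "gait_error_invalid_argument")
  }
  if (!is.null(alignment_prox)) Qp <- apply_alignment(Qp, alignment_prox)
  if (!is.null(alignment_dist)) Qd <- apply_alignment(Qd, alignment_dist)
  Qj <- quat_multiply_rows(quat_conjugate_rows(Qp), Qd)
  ang <- euler_zyx(Qj)
  sgn <- JOINT_SAGITTAL_SIGN[[joint]]
  tibble::tibble(
    time = q_prox$time,
    joint = joint,
    side = side,
    sagittal = unwrap_deg(sgn * ang[, "roll"]),
    frontal = ang[, "yaw"],
    transverse = ang[, "pitch"]
  )
}

#' Pelvic tilt and rotation from the pelvic orientation series
#'
#' Tilt is the sagittal (X) component of the aligned pelvic orientation
#' relative to the global frame (anterior tilt positive); rotation is the
#' transverse (Y) component.
#'
#' @param q_pelvis pelvic orientation tibble.
#' @param alignment `segment_alignment` (or `NULL` if already aligned).
#' @return tibble with columns `time`, `tilt`, `rotation` (degrees).
#' @export
pelvic_angle_series <- function(q_pelvis, alignment = NULL) {
  Q <- cbind(q_pelvis$qw, q_pelvis$qx, q_pelvis$qy, q_pelvis$qz)
  if (!is.null(alignment)) Q <- apply_alignment(Q, alignment)
  ang <- euler_zyx(Q)
  tibble::tibble(
    time = q_pelvis$time,
    tilt = unwrap_deg(ang[, "roll"]),
    rotation = ang[, "pitch"]
  )
}

#' Per-cycle range of motion and the trial-level ROM scalar
#'
#' ROM is max minus min of the angle within each stable gait cycle; the
#' trial scalar is the mean over stable cycles and is the unit of analysis
#' for Bland-Altman comparison against a reference system.
#'
#' @param time,angle the angle series (seconds, degrees).
#' @param cycles cycle tibble from [validate_cycles()].
#' @return list with `per_cycle` (tibble: `start`, `end`, `rom`) and
#'   `trial_mean` (scalar, degrees).
#' @export
cycle_rom <- function(time, angle, cycles) {
  st <- cycles[cycles$stable, , drop = FALSE]
  if (nrow(st) == 0) {
    rlang::abort("no stable cycles", class = "gait_error_insufficient_cycles")
  }
  rom <- vapply(seq_len(nrow(st)), function(i) {
    w <- angle[time >= st$start[i] & time <= st$end[i]]
    if (length(w) == 0) return(NA_real_)
    max(w) - min(w)
  }, numeric(1))
  per_cycle <- tibble::tibble(start = st$start, end = st$end, rom = rom)
  list(per_cycle = per_cycle, trial_mean = mean(rom, na.rm = TRUE))
}
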