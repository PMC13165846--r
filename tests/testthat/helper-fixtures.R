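# shared fixtures, built once per test run

default_truth <- generate_gait_truth(gait_profile())

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  quat_canonical(quat_normalize(q))
}

# orientation RMSE (degrees) of an estimated sensor series against the true
# segment orientation composed with the true mounting misalignment
orientation_rmse <- function(est, truth, node, misalignment = NULL) {
  Q <- as.matrix(est[, c("qw", "qx", "qy", "qz")])
  Qt <- truth$orientations[[node]]
  if (!is.null(misalignment)) {
    Qt <- gaitnet:::quat_multiply_rows(
      Qt, matrix(misalignment, nrow(Qt), 4, byrow = TRUE))
  }
  sqrt(mean(gaitnet:::quat_angle_rows_deg(Q, Qt)^2))
}

# aligned-segment orientation RMSE from a pipeline result
segment_rmse <- function(analysis, truth, node) {
  o <- analysis$orientations[[node]]
  Q <- as.matrix(o[, c("qw", "qx", "qy", "qz")])
  Qa <- gaitnet:::quat_multiply_rows(
    Q, matrix(analysis$alignments[[node]]$q, nrow(Q), 4, byrow = TRUE))
  sqrt(mean(gaitnet:::quat_angle_rows_deg(Qa, truth$orientations[[node]])^2))
}

# per-variable angle RMSE between pipeline output and truth
angle_rmse <- function(analysis, truth) {
  ang <- merge(as.data.frame(analysis$angles), as.data.frame(truth$angles),
               by = c("time", "variable"))
  vapply(split(ang, ang$variable),
         function(d) sqrt(mean((d$value.x - d$value.y)^2)), numeric(1))
}

# event F1 against the truth timeline (50 ms matching window)
event_f1 <- function(detected, truth_events, tol = 0.05) {
  tp <- sum(vapply(seq_len(nrow(truth_events)), function(i) {
    e <- truth_events[i, ]
    any(detected$type == e$type & detected$side == e$side &
          abs(detected$time - e$time) < tol)
  }, logical(1)))
  2 * tp / (nrow(truth_events) + nrow(detected))
}
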