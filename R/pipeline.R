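#' Trial I/O and the end-to-end analysis pipeline
#'
#' A trial is a single long-format CSV: one row per node per sample with
#' columns `time_s`, `node`, `gx gy gz` (rad/s), `ax ay az` (m/s^2),
#' `mx my mz`. All seven placements (pelvis, thigh_l/r, shank_l/r,
#' foot_l/r) must be present for the full pipeline. Units in files are SI;
#' human-facing outputs are in degrees.
#'
#' @name io_pipeline
NULL

TRIAL_COLUMNS <- c("time_s", "node", "gx", "gy", "gz", "ax", "ay", "az",
                   "mx", "my", "mz")

#' Write a trial recording to CSV
#' @param trial trial tibble (`time`, `node`, signal columns).
#' @param path output file.
#' @export
write_trial_csv <- function(trial, path) {
  df <- as.data.frame(trial)
  names(df)[names(df) == "time"] <- "time_s"
  utils::write.csv(df[, TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial recording
#'
#' @param path CSV path.
#' @param require_all_nodes require all seven placements.
#' @param fs expected sampling rate (Hz); gaps longer than 3 sample
#'   periods are reported in a warning.
#' @return `trial_recording` tibble.
#' @export
read_trial_csv <- function(path, require_all_nodes = TRUE, fs = 200) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) rlang::abort(
      sprintf("cannot parse %s: %s", path, conditionMessage(e)),
      class = "gait_error_parse")
  )
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 class = "gait_error_parse")
  }
  bad <- which(!stats::complete.cases(df[, TRIAL_COLUMNS]))
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed row at line %d", bad[1] + 1),
                 class = "gait_error_parse", line = bad[1] + 1)
  }
  if (require_all_nodes) {
    absent <- setdiff(NODE_SEGMENTS, unique(df$node))
    if (length(absent) > 0) {
      rlang::abort(paste("missing node(s):", paste(absent, collapse = ", ")),
                   class = "gait_error_missing_node", nodes = absent)
    }
  }
  for (nd in unique(df$node)) {
    tt <- df$time_s[df$node == nd]
    if (any(diff(tt) <= 0)) {
      rlang::abort(sprintf("out-of-order timestamps for node %s", nd),
                   class = "gait_error_parse")
    }
    if (any(diff(tt) > 3 / fs)) {
      rlang::warn(sprintf("node %s has gaps > 3 sample periods", nd),
                  class = "gait_warning_gaps")
    }
  }
  names(df)[names(df) == "time_s"] <- "time"
  trial <- tibble::as_tibble(df)
  class(trial) <- c("trial_recording", class(trial))
  attr(trial, "fs") <- fs
  trial
}

#' Pipeline configuration
#'
#' Bundles the stage parameters with their standard defaults: the cascade
#' preprocessing windows, the adaptive filter gains, event-detection
#' thresholds and ZUPT settings.
#'
#' @param ncf `ncf_params`.
#' @param cascade list of `cascade_config` per channel group
#'   ([default_cascade_configs()]).
#' @param thresholds `threshold_set` starting values.
#' @param static_window seconds of leading data treated as the static
#'   calibration segment (gyro bias, initial orientation, neutral
#'   alignment).
#' @param stride_method stride-length definition, "projection" or "norm".
#' @param seed seed recorded in reports.
#' @export
pipeline_config <- function(ncf = ncf_params(),
                            cascade = default_cascade_configs(),
                            thresholds = threshold_set(),
                            static_window = 2,
                            stride_method = "projection",
                            seed = 1L) {
  structure(list(ncf = ncf, cascade = cascade, thresholds = thresholds,
                 static_window = static_window,
                 stride_method = stride_method, seed = seed),
            class = "pipeline_config")
}

node_stream <- function(trial, node) {
  out <- trial[trial$node == node, , drop = FALSE]
  if (nrow(out) == 0) {
    rlang::abort(sprintf("missing node %s", node),
                 class = "gait_error_missing_node", nodes = node)
  }
  out
}

#' Per-sample gait-phase labels from a foot event timeline
#'
#' Samples before the first event are labelled "uninitialized"; thereafter
#' the label is "stance" from each heel strike and "swing" from each toe
#' off, until the next event.
#'
#' @param time sample time stamps.
#' @param events single-side event tibble ([detect_events()]).
#' @return character vector of per-sample labels.
#' @export
phase_from_events <- function(time, events) {
  phase <- rep("uninitialized", length(time))
  if (nrow(events) == 0) return(phase)
  ev <- events[order(events$time), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    upto <- if (i < nrow(ev)) time < ev$time[i + 1] else rep(TRUE,
                                                             length(time))
    lab <- if (ev$type[i] == "HS") "stance" else "swing"
    phase[time >= ev$time[i] & upto] <- lab
  }
  phase
}

# vertical specific-force component in the global frame, gravity removed
vertical_accel <- function(stream, orientation, g = STANDARD_GRAVITY) {
  Q <- cbind(orientation$qw, orientation$qx, orientation$qy, orientation$qz)
  A <- quat_rotate_rows(Q, cbind(stream$ax, stream$ay, stream$az))
  A[, 2] - g
}

#' Run the full gait-analysis pipeline on a trial recording
#'
#' Stages: gyro-bias estimation from the static lead-in; cascaded
#' preprocessing; foot orientation bootstrap and event detection; a second
#' orientation pass for all seven nodes with phase-scheduled integral
#' gains; neutral sensor-to-segment alignment; foot-flat detection, ZUPT
#' trajectory reconstruction and spatiotemporal parameters; joint and
#' pelvic angles with per-cycle ROM.
#'
#' @param trial `trial_recording` tibble (all seven nodes).
#' @param config `pipeline_config`.
#' @return list of class `gait_analysis` with elements `orientations`
#'   (per-node tibbles), `alignments`, `events`, `cycles`, `foot_flat`,
#'   `trajectories`, `spatiotemporal`, `angles` (long tibble: `time`,
#'   `variable`, `value` in degrees), `rom` (per-variable trial ROM
#'   scalars), `status` (per-stage status tibble) and `config`.
#' @export
run_pipeline <- function(trial, config = pipeline_config()) {
  status <- list()
  note <- function(stage, state, detail = "") {
    status[[length(status) + 1]] <<- tibble::tibble(
      stage = stage, state = state, detail = detail)
  }
  fs <- attr(trial, "fs") %||% 200

  streams <- lapply(stats::setNames(NODE_SEGMENTS, NODE_SEGMENTS),
                    function(nd) node_stream(trial, nd))
  t0 <- min(trial$time)

  # ---- calibration from the static lead-in -------------------------------
  biases <- lapply(streams, function(s) {
    idx <- s$time <= t0 + config$static_window
    tryCatch(estimate_gyro_bias(s[idx, ], fs = fs),
             gait_error_not_static = function(e) c(gx = 0, gy = 0, gz = 0))
  })
  note("calibration", "ok")

  # ---- preprocessing ------------------------------------------------------
  streams <- lapply(streams, function(s) {
    for (ch in c("gx", "gy", "gz")) {
      s[[ch]] <- cascade_filter(s[[ch]], config$cascade$gyro)
    }
    for (ch in c("ax", "ay", "az")) {
      s[[ch]] <- cascade_filter(s[[ch]], config$cascade$accel)
    }
    for (ch in c("mx", "my", "mz")) {
      s[[ch]] <- cascade_filter(s[[ch]], config$cascade$mag)
    }
    s
  })
  # subtract the estimated gyro bias once here; the filter then runs with
  # zero residual bias and its integral term absorbs any remainder
  for (nd in NODE_SEGMENTS) {
    b <- biases[[nd]]
    streams[[nd]]$gx <- streams[[nd]]$gx - b[1]
    streams[[nd]]$gy <- streams[[nd]]$gy - b[2]
    streams[[nd]]$gz <- streams[[nd]]$gz - b[3]
  }
  note("preprocess", "ok")

  # ---- foot orientation bootstrap + event detection -----------------------
  orientations <- list()
  alignments <- list()
  events_by_side <- list()
  for (side in c("l", "r")) {
    nd <- paste0("foot_", side)
    s <- streams[[nd]]
    q_boot <- estimate_orientation(s, params = config$ncf)
    align <- compute_neutral_alignment(
      as.matrix(q_boot[s$time <= t0 + config$static_window,
                       c("qw", "qx", "qy", "qz")]),
      segment = nd)
    a_vert <- vertical_accel(s, q_boot)
    omega_seg <- quat_rotate_rows_inv(
      matrix(align$q, nrow(s), 4, byrow = TRUE), cbind(s$gx, s$gy, s$gz))
    side_name <- if (side == "l") "left" else "right"
    ev <- detect_events(a_vert, omega_seg[, 1], config$thresholds, fs = fs,
                        side = side_name, time = s$time)
    events_by_side[[side_name]] <- ev
  }
  events <- dplyr::arrange(dplyr::bind_rows(events_by_side), .data$time)
  note("events", if (nrow(events) > 0) "ok" else "no-events")

  # ---- second orientation pass with phase scheduling ----------------------
  foot_flat <- list()
  for (side in c("l", "r")) {
    nd <- paste0("foot_", side)
    side_name <- if (side == "l") "left" else "right"
    ph <- phase_from_events(streams[[nd]]$time, events_by_side[[side_name]])
    orientations[[nd]] <- estimate_orientation(streams[[nd]], phase = ph,
                                               params = config$ncf)
    foot_flat[[side_name]] <- detect_foot_flat(streams[[nd]],
                                               events_by_side[[side_name]])
  }
  for (side in c("l", "r")) {
    side_name <- if (side == "l") "left" else "right"
    for (seg in c("thigh_", "shank_")) {
      nd <- paste0(seg, side)
      ph <- phase_from_events(streams[[nd]]$time,
                              events_by_side[[side_name]])
      orientations[[nd]] <- estimate_orientation(streams[[nd]], phase = ph,
                                                 params = config$ncf)
    }
  }
  # pelvis: stance-like whenever either foot is inside a foot-flat interval
  tt_p <- streams$pelvis$time
  in_flat <- rep(FALSE, length(tt_p))
  for (ffl in foot_flat) {
    for (i in seq_len(nrow(ffl))) {
      in_flat <- in_flat | (tt_p >= ffl$start[i] & tt_p <= ffl$end[i])
    }
  }
  ph_p <- ifelse(in_flat, "stance", "swing")
  ph_p[tt_p <= t0 + config$static_window] <- "uninitialized"
  orientations$pelvis <- estimate_orientation(streams$pelvis, phase = ph_p,
                                              params = config$ncf)
  note("orientation", "ok")

  # ---- neutral alignment --------------------------------------------------
  for (nd in NODE_SEGMENTS) {
    qst <- orientations[[nd]]
    idx <- qst$time >= t0 + config$static_window / 2 &
      qst$time <= t0 + config$static_window
    alignments[[nd]] <- compute_neutral_alignment(
      as.matrix(qst[idx, c("qw", "qx", "qy", "qz")]), segment = nd)
  }
  note("alignment", "ok")

  # ---- trajectories and spatiotemporal parameters -------------------------
  trajectories <- list()
  spatiotemporal <- NULL
  for (side in c("l", "r")) {
    nd <- paste0("foot_", side)
    side_name <- if (side == "l") "left" else "right"
    trajectories[[side_name]] <- reconstruct_trajectory(
      streams[[nd]], orientations[[nd]], foot_flat[[side_name]],
      events = events_by_side[[side_name]])
  }
  spatiotemporal <- tryCatch(
    spatiotemporal_params(trajectories$left, trajectories$right, events,
                          stride_method = config$stride_method),
    gait_error_insufficient_strides = function(e) {
      note("spatiotemporal", "insufficient-strides", conditionMessage(e))
      NULL
    })
  if (!is.null(spatiotemporal)) note("spatiotemporal", "ok")

  # ---- kinematics ---------------------------------------------------------
  angles <- list()
  for (side in c("l", "r")) {
    suffix <- paste0("_", side)
    side_name <- if (side == "l") "left" else "right"
    hip <- joint_angle_series(orientations$pelvis,
                              orientations[[paste0("thigh", suffix)]],
                              alignments$pelvis,
                              alignments[[paste0("thigh", suffix)]],
                              joint = "hip", side = side_name)
    knee <- joint_angle_series(orientations[[paste0("thigh", suffix)]],
                               orientations[[paste0("shank", suffix)]],
                               alignments[[paste0("thigh", suffix)]],
                               alignments[[paste0("shank", suffix)]],
                               joint = "knee", side = side_name)
    ankle <- joint_angle_series(orientations[[paste0("shank", suffix)]],
                                orientations[[paste0("foot", suffix)]],
                                alignments[[paste0("shank", suffix)]],
                                alignments[[paste0("foot", suffix)]],
                                joint = "ankle", side = side_name)
    for (ja in list(hip, knee, ankle)) {
      angles[[length(angles) + 1]] <- tibble::tibble(
        time = ja$time, variable = paste0(ja$joint[1], suffix),
        value = ja$sagittal)
    }
  }
  pel <- pelvic_angle_series(orientations$pelvis, alignments$pelvis)
  angles[[length(angles) + 1]] <- tibble::tibble(
    time = pel$time, variable = "pelvic_tilt", value = pel$tilt)
  angles[[length(angles) + 1]] <- tibble::tibble(
    time = pel$time, variable = "pelvic_rotation", value = pel$rotation)
  angles <- dplyr::bind_rows(angles)
  note("kinematics", "ok")

  cycles <- dplyr::bind_rows(lapply(events_by_side, validate_cycles))
  rom <- tryCatch({
    dplyr::bind_rows(lapply(split(angles, angles$variable), function(df) {
      side_cycles <- cycles[cycles$side == ifelse(grepl("_r$", df$variable[1]),
                                                  "right", "left"), ,
                            drop = FALSE]
      if (nrow(side_cycles) == 0) return(NULL)
      r <- tryCatch(cycle_rom(df$time, df$value, side_cycles),
                    gait_error_insufficient_cycles = function(e) NULL)
      if (is.null(r)) return(NULL)
      tibble::tibble(variable = df$variable[1], rom_mean = r$trial_mean,
                     n_cycles = nrow(r$per_cycle))
    }))
  }, error = function(e) NULL)

  structure(list(
    orientations = orientations, alignments = alignments,
    events = events, cycles = cycles, foot_flat = foot_flat,
    trajectories = trajectories, spatiotemporal = spatiotemporal,
    angles = angles, rom = rom,
    status = dplyr::bind_rows(status), config = config
  ), class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("Gait analysis result\n")
  cat(sprintf("  events: %d (%d left / %d right)\n", nrow(x$events),
              sum(x$events$side == "left"), sum(x$events$side == "right")))
  if (!is.null(x$spatiotemporal)) print(x$spatiotemporal)
  cat("  kinematic variables:",
      paste(unique(x$angles$variable), collapse = ", "), "\n")
  invisible(x)
}

#' Compare pipeline kinematics with a reference angle data set
#'
#' Aligns the estimated and reference series with a cross-correlation lag
#' search on the pelvic angular-rate magnitude channel (computed from the
#' pelvic angle derivatives on both sides, avoiding circular dependence on
#' the variables under validation), then computes agreement statistics per
#' kinematic variable on the common 100 Hz base.
#'
#' @param analysis `gait_analysis` result.
#' @param reference long tibble (`time`, `variable`, `value`) as produced
#'   by [synthesize_reference()] or read from a reference CSV.
#' @param fs_out common comparison rate, Hz.
#' @param variables variables to compare (default: all shared).
#' @return tibble with one `agreement_report` row per variable plus columns
#'   `variable` and `lag_s`.
#' @export
compare_with_reference <- function(analysis, reference, fs_out = 100,
                                   variables = NULL) {
  ang <- analysis$angles
  shared <- intersect(unique(ang$variable), unique(reference$variable))
  if (is.null(variables)) variables <- shared
  variables <- intersect(variables, shared)
  if (length(variables) == 0) {
    rlang::abort("no shared variables to compare",
                 class = "gait_error_invalid_argument")
  }

  rate_channel <- function(df) {
    tilt <- df[df$variable == "pelvic_tilt", , drop = FALSE]
    rot <- df[df$variable == "pelvic_rotation", , drop = FALSE]
    fs <- 1 / stats::median(diff(tilt$time))
    # low-pass before differencing, as in the marker-processing protocol:
    # differentiation amplifies sample noise far above the gait band
    ts <- zero_lag_butterworth(tilt$value, fs)
    rs <- zero_lag_butterworth(rot$value, fs)
    v <- sqrt(c(0, diff(ts) / diff(tilt$time))^2 +
                c(0, diff(rs) / diff(rot$time))^2)
    tibble::tibble(time = tilt$time, value = v)
  }
  pair <- align_by_xcorr(rate_channel(ang), rate_channel(reference),
                         fs_out = fs_out)
  lag <- pair$lag

  dplyr::bind_rows(lapply(variables, function(v) {
    tst <- ang[ang$variable == v, , drop = FALSE]
    ref <- reference[reference$variable == v, , drop = FALSE]
    grid <- pair$time
    ts <- stats::approx(tst$time + lag, tst$value, xout = grid)$y
    rs <- stats::approx(ref$time, ref$value, xout = grid)$y
    keep <- !is.na(ts) & !is.na(rs)
    rep <- agreement_metrics(ts[keep], rs[keep])
    dplyr::bind_cols(tibble::tibble(variable = v, lag_s = lag), rep)
  }))
}

#' Simulate a trial and write its fixture files
#'
#' Writes the trial CSV (IMU streams), a truth angle CSV and a reference
#' angle CSV into a directory; the programmatic equivalent of the CLI
#' `simulate` subcommand.
#'
#' @param out_dir output directory (created if needed).
#' @param profile `gait_profile`.
#' @param noise `noise_model`.
#' @param reference_lag_s injected reference lag, seconds.
#' @param seed seed for noise synthesis (overrides `noise$seed`).
#' @return invisible list of written paths.
#' @export
simulate_trial_files <- function(out_dir, profile = gait_profile(),
                                 noise = noise_model(),
                                 reference_lag_s = 0.2, seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) noise$seed <- seed
  truth <- generate_gait_truth(profile)
  trial <- synthesize_imu(truth, noise)
  ref <- synthesize_reference(truth, lag_s = reference_lag_s,
                              seed = noise$seed)
  paths <- list(
    trial = file.path(out_dir, "trial.csv"),
    truth = file.path(out_dir, "truth_angles.csv"),
    reference = file.path(out_dir, "reference.csv"),
    events = file.path(out_dir, "truth_events.csv")
  )
  write_trial_csv(trial, paths$trial)
  utils::write.csv(truth$angles, paths$truth, row.names = FALSE)
  utils::write.csv(ref, paths$reference, row.names = FALSE)
  utils::write.csv(truth$events, paths$events, row.names = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
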