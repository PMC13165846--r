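#' Plot kinematic angle series of a gait analysis
#'
#' Sagittal joint and pelvic angle traces over time, faceted by variable,
#' with detected heel strikes and toe offs overlaid.
#'
#' @param object `gait_analysis`.
#' @param variables subset of variables to show (default all).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gait_analysis <- function(object, variables = NULL, ...) {
  ang <- object$angles
  if (!is.null(variables)) ang <- ang[ang$variable %in% variables, ]
  p <- ggplot2::ggplot(ang, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$events,
      ggplot2::aes(xintercept = .data$time, colour = .data$type),
      alpha = 0.25, linewidth = 0.2)
  }
  p
}

#' Bland-Altman plot of an agreement report
#'
#' @param object `agreement_report` (with the per-pair data attached).
#' @param ... unused.
#' @return a ggplot object: pairwise means vs differences with the bias and
#'   95% limits of agreement.
#' @export
autoplot.agreement_report <- function(object, ...) {
  ba <- attr(object, "bland_altman")
  ggplot2::ggplot(ba, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of methods", y = "difference (test - reference)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.agreement_report
#' @export
plot_bland_altman <- function(object, ...) autoplot(object, ...)

#' Plot a reconstructed foot trajectory
#'
#' Sagittal-plane (forward vs vertical) path with foot-flat anchor
#' intervals marked on the forward-velocity trace.
#'
#' @param object `foot_trajectory`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.foot_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pz, y = .data$py)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::labs(x = "forward position (m)", y = "vertical position (m)") +
    ggplot2::theme_minimal()
}

#' Plot detected gait events over the vertical-acceleration signal
#'
#' @param a_vert vertical acceleration series, m/s^2.
#' @param events event tibble from [detect_events()].
#' @param time time stamps (defaults to the event tibble's sample indices).
#' @param fs sampling rate used when `time` is absent.
#' @return a ggplot object.
#' @export
plot_events <- function(a_vert, events, time = NULL, fs = 200) {
  if (is.null(time)) time <- (seq_along(a_vert) - 1) / fs
  df <- tibble::tibble(time = time, a_vert = a_vert)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$a_vert)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = events,
                        ggplot2::aes(xintercept = .data$time,
                                     colour = .data$type),
                        alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "vertical acceleration (m/s^2)") +
    ggplot2::theme_minimal()
}
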