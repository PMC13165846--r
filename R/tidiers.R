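#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the kinematic output of a gait analysis
#'
#' @param x `gait_analysis`.
#' @param ... unused.
#' @return long tibble `time`, `variable`, `value` (degrees).
#' @export
tidy.gait_analysis <- function(x, ...) {
  x$angles
}

#' One-row summary of a gait analysis
#'
#' @param x `gait_analysis`.
#' @param ... unused.
#' @return one-row tibble: event counts, spatiotemporal summary, stable
#'   cycle count.
#' @export
glance.gait_analysis <- function(x, ...) {
  st <- if (!is.null(x$spatiotemporal)) x$spatiotemporal$summary else
    tibble::tibble(stride_length_m = NA_real_, step_width_m = NA_real_,
                   cadence_spm = NA_real_, velocity_ms = NA_real_,
                   cycle_time_s = NA_real_, n_steps = NA_integer_)
  dplyr::bind_cols(
    tibble::tibble(n_events = nrow(x$events),
                   n_stable_cycles = sum(x$cycles$stable)),
    st
  )
}

#' Tidy an agreement report into metric/value pairs
#'
#' @param x `agreement_report`.
#' @param ... unused.
#' @export
tidy.agreement_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.spatiotemporal <- function(x, ...) {
  x$summary
}
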