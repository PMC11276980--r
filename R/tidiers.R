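#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for fitted result objects
#'
#' `tidy()` returns one row per component (parameter, sweep, pulse or
#' value); `glance()` returns a one-row summary. Both return tibbles, so
#' results drop straight into dplyr pipelines.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name epislice-tidiers
NULL

#' @rdname epislice-tidiers
#' @method tidy passive_properties
#' @export
tidy.passive_properties <- function(x, ...) {
  tibble(
    term = c("rmp", "r_in", "tau_m"),
    estimate = c(x$rmp, x$r_in, x$tau_m),
    unit = c("mV", "MOhm", "ms")
  )
}

#' @rdname epislice-tidiers
#' @method glance passive_properties
#' @export
glance.passive_properties <- function(x, ...) {
  tibble(rmp = x$rmp, r_in = x$r_in, tau_m = x$tau_m)
}

#' @rdname epislice-tidiers
#' @method tidy firing_pattern
#' @export
tidy.firing_pattern <- function(x, ...) x$fi_curve

#' @rdname epislice-tidiers
#' @method glance firing_pattern
#' @export
glance.firing_pattern <- function(x, ...) {
  tibble(
    rheobase = x$rheobase, time_of_first_spike = x$time_of_first_spike,
    max_rate = x$max_rate, current_at_max = x$current_at_max,
    block_current = x$block_current, max_fi_slope = x$max_fi_slope,
    early_adaptation = x$early_adaptation, late_adaptation = x$late_adaptation
  )
}

#' @rdname epislice-tidiers
#' @method tidy outlier_screen
#' @export
tidy.outlier_screen <- function(x, ...) tibble::as_tibble(x)

#' @rdname epislice-tidiers
#' @method glance outlier_screen
#' @export
glance.outlier_screen <- function(x, ...) {
  tibble(
    n = nrow(x), n_flagged = sum(x$flag), threshold = attr(x, "threshold")
  )
}

#' @rdname epislice-tidiers
#' @method tidy evoked_responses
#' @export
tidy.evoked_responses <- function(x, ...) {
  dplyr::mutate(x$measurements, normalized = x$normalized)
}

#' @rdname epislice-tidiers
#' @method glance evoked_responses
#' @export
glance.evoked_responses <- function(x, ...) {
  tibble(
    n_pulses = length(x$amplitudes), amplitude_1 = x$amplitudes[1],
    ppr = x$ppr, pathway = x$pathway
  )
}

#' @rdname epislice-tidiers
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$groups

#' @rdname epislice-tidiers
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(t_statistic = x$t_statistic, df = x$df, p_value = x$p_value)
}

#' @rdname epislice-tidiers
#' @method tidy iei_summary
#' @export
tidy.iei_summary <- function(x, ...) x$histogram

#' @rdname epislice-tidiers
#' @method glance iei_summary
#' @export
glance.iei_summary <- function(x, ...) {
  tibble(
    n_intervals = length(x$intervals),
    mode_1_s = x$modes[1],
    mode_2_s = if (length(x$modes) > 1) x$modes[2] else NA_real_
  )
}
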