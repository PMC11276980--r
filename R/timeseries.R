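#' Construct a uniformly sampled time series
#'
#' The basic signal container used throughout the package: a tibble with
#' columns `time_s` and `value`, carrying the sampling rate, physical units
#' and a channel label as attributes. Voltages are in mV, currents in pA;
#' local field potentials, whose absolute calibration is typically unknown,
#' use arbitrary units (`"a.u."`). All downstream LFP processing is invariant
#' to positive rescaling of the signal, so arbitrary units are safe.
#'
#' @param value numeric vector of samples (mV, pA or a.u.).
#' @param rate sampling rate in Hz; must be positive.
#' @param t0 time of the first sample in seconds (default 0).
#' @param units one of `"mV"`, `"pA"`, `"a.u."`.
#' @param label channel label.
#' @return A tibble of class `eps_ts` with columns `time_s`, `value`.
#' @examples
#' ts <- timeseries(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), rate = 1000)
#' ts_rate(ts)
#' @export
timeseries <- function(value, rate, t0 = 0, units = c("a.u.", "mV", "pA"),
                       label = "signal") {
  units <- match.arg(units)
  if (!is.numeric(value) || length(value) < 2L) {
    abort("a time series needs at least 2 numeric samples")
  }
  if (!all(is.finite(value))) abort("corrupt signal: non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("unspecified sampling rate")
  }
  out <- tibble(
    time_s = t0 + (seq_along(value) - 1) / rate,
    value = as.numeric(value)
  )
  structure(out,
    class = c("eps_ts", class(out)),
    rate = as.numeric(rate), t0 = as.numeric(t0),
    units = units, label = as.character(label)
  )
}

#' @rdname timeseries
#' @param ts an `eps_ts` object.
#' @export
ts_rate <- function(ts) attr(ts, "rate")

#' @rdname timeseries
#' @export
ts_units <- function(ts) attr(ts, "units")

#' @rdname timeseries
#' @export
ts_label <- function(ts) attr(ts, "label")

#' @rdname timeseries
#' @export
ts_t0 <- function(ts) attr(ts, "t0")

#' @rdname timeseries
#' @export
ts_duration <- function(ts) nrow(ts) / ts_rate(ts)

validate_timeseries <- function(ts) {
  if (!inherits(ts, "eps_ts")) abort("not a timeseries (eps_ts) object")
  if (is.null(ts_rate(ts)) || !is.finite(ts_rate(ts)) || ts_rate(ts) <= 0) {
    abort("unspecified sampling rate")
  }
  if (nrow(ts) < 2L) abort("a time series needs at least 2 samples")
  if (!all(is.finite(ts$value))) abort("corrupt signal: non-finite samples")
  invisible(ts)
}

# rebuild an eps_ts from samples while keeping metadata
ts_like <- function(value, template, rate = ts_rate(template)) {
  timeseries(value,
    rate = rate, t0 = ts_t0(template),
    units = ts_units(template), label = ts_label(template)
  )
}

#' Rectangular current-step protocol description
#'
#' Describes a family of current-clamp sweeps: a rectangular step of fixed
#' onset and duration whose amplitude varies across sweeps. Default values
#' follow common practice for characterizing CA1 pyramidal cells: 1.5 s
#' steps delivered every 3.5 s, amplitudes from -100 to +600 pA.
#'
#' @param step_onset step onset within the sweep, s.
#' @param step_duration step duration, s.
#' @param amplitudes injected current per sweep, pA.
#' @param inter_sweep_interval time between sweep onsets, s.
#' @return a `step_protocol` list.
#' @export
step_protocol <- function(step_onset = 0.25, step_duration = 1.5,
                          amplitudes = seq(-100, 600, by = 20),
                          inter_sweep_interval = 3.5) {
  if (step_onset < 0) abort("step_onset must be >= 0")
  if (step_duration <= 0) abort("step_duration must be > 0")
  if (!all(is.finite(amplitudes))) abort("amplitudes must be finite")
  structure(
    list(
      step_onset = step_onset, step_duration = step_duration,
      amplitudes = as.numeric(amplitudes),
      inter_sweep_interval = inter_sweep_interval
    ),
    class = "step_protocol"
  )
}

#' Construct a sweep family
#'
#' A long-format tibble of current-clamp sweeps (one voltage trace per
#' injected current amplitude), the substrate for passive-property and
#' firing-pattern analysis.
#'
#' @param sweeps list of `eps_ts` voltage traces, one per protocol amplitude.
#' @param protocol a [step_protocol()].
#' @return tibble of class `eps_sweeps` with columns `sweep`, `amplitude_pa`,
#'   `time_s`, `v_mv`; the protocol and sampling rate ride along as
#'   attributes.
#' @export
sweep_family <- function(sweeps, protocol) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (length(sweeps) != length(protocol$amplitudes)) {
    abort("one sweep per protocol amplitude required")
  }
  rates <- vapply(sweeps, ts_rate, numeric(1))
  lens <- vapply(sweeps, nrow, integer(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L) {
    abort("all sweeps must share sampling rate and length")
  }
  out <- purrr::map2_dfr(sweeps, seq_along(sweeps), function(s, i) {
    tibble(
      sweep = i, amplitude_pa = protocol$amplitudes[i],
      time_s = s$time_s, v_mv = s$value
    )
  })
  structure(out,
    class = c("eps_sweeps", class(out)),
    rate = rates[1], protocol = protocol
  )
}

#' @rdname sweep_family
#' @param family an `eps_sweeps` object.
#' @export
family_protocol <- function(family) attr(family, "protocol")

#' @rdname sweep_family
#' @export
family_rate <- function(family) attr(family, "rate")

# extract one sweep as an eps_ts voltage trace
family_sweep <- function(family, i) {
  v <- family$v_mv[family$sweep == i]
  timeseries(v, rate = family_rate(family), units = "mV",
             label = paste0("sweep", i))
}

#' Stimulus markers for evoked-response protocols
#'
#' @param times stimulus onset times, s (strictly increasing).
#' @param pathway stimulated pathway label: `"schaffer"`, `"temporoammonic"`
#'   or `"other"`.
#' @return tibble of class `eps_stims` with column `time_s`.
#' @export
stim_markers <- function(times, pathway = c("other", "schaffer", "temporoammonic")) {
  pathway <- match.arg(pathway)
  if (length(times) && any(diff(times) <= 0)) {
    abort("stimulus times must be strictly increasing")
  }
  out <- tibble(time_s = as.numeric(times))
  structure(out, class = c("eps_stims", class(out)), pathway = pathway)
}
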