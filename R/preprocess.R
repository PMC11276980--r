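#' Detection pipeline configuration
#'
#' Parameters of the unitary-epileptiform-event (uEE) detector: an 8th-order
#' lowpass Butterworth prefilter bringing the signal down to a 200 Hz
#' sampling rate, an amplitude threshold at the 99th percentile of the
#' rectified amplitude distribution, and a 50 ms refractory lockout that
#' collapses repeated threshold exceedances within a single discharge into
#' one event.
#'
#' @param filter_order Butterworth order (default 8).
#' @param target_rate output sampling rate after decimation, Hz (default
#'   200); the anti-alias cutoff is `target_rate / 2`.
#' @param threshold_percentile amplitude percentile used as threshold
#'   (default 99).
#' @param lockout refractory lockout in seconds (default 0.05).
#' @param polarity which deflections are thresholded: `"absolute"`
#'   (rectified, default - robust to electrode polarity), `"positive"` or
#'   `"negative"`.
#' @param highpass optional drift-removal high-pass corner in Hz applied
#'   before thresholding; `NULL` (default) disables it.
#' @return a `detection_config` list.
#' @export
detection_config <- function(filter_order = 8L, target_rate = 200,
                             threshold_percentile = 99, lockout = 0.05,
                             polarity = c("absolute", "positive", "negative"),
                             highpass = NULL) {
  polarity <- match.arg(polarity)
  if (threshold_percentile <= 0 || threshold_percentile >= 100) {
    abort("threshold_percentile must lie in (0, 100)")
  }
  if (lockout <= 0) abort("lockout must be > 0")
  if (filter_order < 1) abort("filter_order must be >= 1")
  structure(
    list(
      filter_order = as.integer(filter_order), target_rate = target_rate,
      threshold_percentile = threshold_percentile, lockout = lockout,
      polarity = polarity, highpass = highpass
    ),
    class = "detection_config"
  )
}

# Lowpass Butterworth as second-order sections: analog prototype poles,
# bilinear transform, conjugate pole pairs -> biquads with unity DC gain.
# Odd orders contribute one first-order section (expressed as a degenerate
# biquad). Returns matrix with columns b0 b1 b2 a1 a2.
butter_sos <- function(order, fc, fs) {
  wc <- 2 * fs * tan(pi * fc / fs) # prewarped analog cutoff (rad/s)
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  poles <- wc * exp(1i * theta) # analog Butterworth poles, left half-plane
  zp <- (2 * fs + poles) / (2 * fs - poles) # bilinear
  # pair conjugates: poles come in conjugate pairs except none for lowpass
  # of even order; take those with positive imaginary part (+ real ones)
  realp <- zp[abs(Im(zp)) < 1e-12]
  cplxp <- zp[Im(zp) > 1e-12]
  sos <- matrix(0, nrow = 0, ncol = 5)
  for (p in cplxp) {
    a1 <- -2 * Re(p)
    a2 <- Mod(p)^2
    g <- (1 + a1 + a2) / 4 # unity gain at DC, numerator (1 + z^-1)^2
    sos <- rbind(sos, c(g, 2 * g, g, a1, a2))
  }
  for (p in Re(realp)) {
    a1 <- -p
    g <- (1 + a1) / 2 # numerator (1 + z^-1)
    sos <- rbind(sos, c(g, g, 0, a1, 0))
  }
  sos
}

# first-order zero-phase high-pass (drift removal)
highpass_zero_phase <- function(x, fc, fs) {
  a <- exp(-2 * pi * fc / fs)
  g <- (1 + a) / 2
  sos <- matrix(c(g, -g, 0, -a, 0), nrow = 1)
  sos_filtfilt_cpp(x, sos, pad = min(length(x) - 1L, as.integer(3 * fs / fc)))
}

#' Prefilter and decimate an LFP recording
#'
#' Applies a zero-phase (forward-backward) lowpass Butterworth filter of the
#' configured order with cutoff at `target_rate / 2` (anti-alias), then
#' decimates to exactly `target_rate`. Zero-phase filtering is used so that
#' event onset times, the quantity the detector measures, are not delayed by
#' the filter; the effective magnitude response is the squared Butterworth
#' magnitude.
#'
#' @param lfp an [timeseries()]; `ts_rate(lfp)` must be at least
#'   `2 * target_rate` and an integer multiple of it. A signal already at
#'   `target_rate` is returned unchanged.
#' @param cfg a [detection_config()].
#' @return an `eps_ts` sampled at `cfg$target_rate`, same duration as the
#'   input to within one output sample.
#' @export
preprocess <- function(lfp, cfg = detection_config()) {
  validate_timeseries(lfp)
  fs <- ts_rate(lfp)
  if (abs(fs - cfg$target_rate) < 1e-9) return(lfp) # already at target rate
  if (fs < 2 * cfg$target_rate) abort("insufficient sampling rate")
  factor <- fs / cfg$target_rate
  if (abs(factor - round(factor)) > 1e-6) {
    abort("sampling rate must be an integer multiple of target_rate")
  }
  factor <- as.integer(round(factor))
  fc <- cfg$target_rate / 2
  x <- lfp$value
  if (factor > 1L) {
    sos <- butter_sos(cfg$filter_order, fc, fs)
    pad <- min(length(x) - 1L, as.integer(6 * fs / fc))
    x <- sos_filtfilt_cpp(x, sos, pad)
    x <- x[seq(1L, length(x), by = factor)]
  }
  if (!is.null(cfg$highpass)) {
    x <- highpass_zero_phase(x, cfg$highpass, cfg$target_rate)
  }
  ts_like(x, lfp, rate = cfg$target_rate)
}
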