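#' Detect action potentials by voltage slope
#'
#' The AP voltage threshold is the point at which the first derivative of
#' the voltage (dV/dt, centered differences) exceeds `dvdt_threshold`
#' (default 5 mV/ms). A candidate crossing counts as a spike onset only if a
#' genuine AP follows: the voltage must rise at least 20 mV above the onset
#' within 5 ms. Onsets closer than 1 ms to the previous accepted onset are
#' discarded.
#'
#' @param sweep an [timeseries()] voltage trace (mV); sampling at 10 kHz or
#'   above is recommended for derivative accuracy.
#' @param dvdt_threshold slope threshold, mV/ms.
#' @param smooth optional zero-phase 2 kHz lowpass applied to the derivative
#'   estimate before thresholding (off by default).
#' @return tibble of class `eps_spikes` with column `t_thr` (threshold
#'   crossing times, s).
#' @export
detect_spikes <- function(sweep, dvdt_threshold = 5, smooth = FALSE) {
  validate_timeseries(sweep)
  fs <- ts_rate(sweep)
  v <- sweep$value
  if (isTRUE(smooth) && fs > 8000) {
    sos <- butter_sos(4, 2000, fs)
    v <- sos_filtfilt_cpp(v, sos, pad = min(length(v) - 1L, as.integer(fs / 200)))
  }
  dvdt <- dvdt_mvms(v, fs)
  above <- dvdt >= dvdt_threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  win5 <- max(1L, round(0.005 * fs))
  onsets <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if ((i - last) / fs < 0.001) next
    j1 <- min(length(v), i + win5)
    if (max(v[i:j1]) - v[i] >= 20) {
      onsets <- c(onsets, (i - 1) / fs + ts_t0(sweep))
      last <- i
    }
  }
  out <- tibble(t_thr = onsets)
  structure(out, class = c("eps_spikes", class(out)), rate = fs)
}

# centered-difference derivative in mV/ms (v in mV, fs in Hz)
dvdt_mvms <- function(v, fs) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2000
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

# linear interpolation of the time at which v crosses `level` between
# samples i and i+1
cross_time <- function(t, v, i, level) {
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Action-potential waveform features
#'
#' Measures the standard per-spike quantities, all relative to the AP
#' voltage threshold except where stated: amplitude (peak minus threshold),
#' 10-90% rise time on the rising phase, half-width at half amplitude (with
#' linear interpolation of the crossing times), fAHP (voltage at the first
#' post-peak point where the decay slows to less than `dvdt_threshold`
#' mV/ms), mAHP (lowest voltage after the peak, relative to threshold), time
#' from the fAHP to the mAHP peak, and ADP (peak voltage between the fAHP
#' and mAHP points, relative to the fAHP voltage).
#'
#' The analysis window runs from `onset` to `next_onset` (or `onset` +
#' `window` when there is no next spike). If the window is cut before a
#' credible mAHP trough, the AHP-dependent features are reported missing
#' with a `"incomplete AHP window"` warning rather than guessed.
#'
#' @param sweep an [timeseries()] voltage trace, mV.
#' @param onset spike onset time from [detect_spikes()], s.
#' @param next_onset onset of the following spike, s, or `NULL`.
#' @param dvdt_threshold slope criterion for the fAHP point, mV/ms.
#' @param window maximum window length after onset, s.
#' @return one-row tibble of class `eps_apf`: `threshold_v`, `threshold_t`,
#'   `amplitude`, `rise_10_90` (ms), `half_width` (ms), `fahp`, `mahp`
#'   (mV, relative to threshold), `time_to_mahp` (ms), `adp` (mV).
#' @export
ap_features <- function(sweep, onset, next_onset = NULL, dvdt_threshold = 5,
                        window = 0.150) {
  validate_timeseries(sweep)
  fs <- ts_rate(sweep)
  t <- sweep$time_s
  v <- sweep$value
  i_on <- which.min(abs(t - onset))
  t_end <- min(
    if (is.null(next_onset)) Inf else next_onset,
    onset + window, t[length(t)]
  )
  i_end <- max(which(t <= t_end))
  if (i_end - i_on < 4L) {
    warn("incomplete AHP window")
    return(apf_row(v[i_on], onset, rep(NA_real_, 7)))
  }
  thr_v <- v[i_on]

  # AP peak: maximum within the first 10 ms of the window
  i_pk_end <- min(i_end, i_on + round(0.01 * fs))
  i_peak <- i_on + which.max(v[i_on:i_pk_end]) - 1L
  if (i_end - i_peak < 3L) {
    # window ends on or immediately after the rising phase
    warn("incomplete AHP window")
    return(apf_row(thr_v, onset, rep(NA_real_, 7)))
  }
  amp <- v[i_peak] - thr_v

  # rising-phase crossings (linear interpolation)
  lev10 <- thr_v + 0.1 * amp
  lev90 <- thr_v + 0.9 * amp
  seg <- i_on:i_peak
  r10 <- first_cross_up(t, v, seg, lev10)
  r90 <- first_cross_up(t, v, seg, lev90)
  rise <- 1000 * (r90 - r10)

  lev50 <- thr_v + amp / 2
  t_up <- first_cross_up(t, v, seg, lev50)
  post <- i_peak:i_end
  t_dn <- first_cross_down(t, v, post, lev50)
  half_width <- 1000 * (t_dn - t_up)

  # fAHP: decay must first exceed the slope criterion, then slow below it
  dvdt <- dvdt_mvms(v[i_peak:i_end], fs)
  fast <- which(dvdt < -dvdt_threshold)
  fahp <- mahp <- t2m <- adp <- NA_real_
  i_fahp <- NA_integer_
  if (length(fast)) {
    slow <- which(dvdt[-seq_len(fast[1])] >= -dvdt_threshold)
    if (length(slow)) {
      i_fahp <- i_peak + fast[1] + slow[1] - 1L
      fahp <- v[i_fahp] - thr_v
    }
  }
  i_min <- i_peak + which.min(v[i_peak:i_end]) - 1L
  if (i_min >= i_end - 1L || is.na(i_fahp)) {
    warn("incomplete AHP window")
  } else {
    mahp <- v[i_min] - thr_v
    t2m <- 1000 * (t[i_min] - t[i_fahp])
    if (i_min > i_fahp + 1L) {
      adp <- max(v[i_fahp:i_min]) - v[i_fahp]
    } else {
      adp <- 0
    }
  }
  apf_row(thr_v, onset, c(amp, rise, half_width, fahp, mahp, t2m, adp))
}

apf_row <- function(thr_v, onset, rest) {
  out <- tibble(
    threshold_v = thr_v, threshold_t = onset, amplitude = rest[1],
    rise_10_90 = rest[2], half_width = rest[3], fahp = rest[4],
    mahp = rest[5], time_to_mahp = rest[6], adp = rest[7]
  )
  structure(out, class = c("eps_apf", class(out)))
}

first_cross_up <- function(t, v, idx, level) {
  rel <- v[idx]
  k <- which(rel[-1] >= level & rel[-length(rel)] < level)
  if (!length(k)) return(NA_real_)
  cross_time(t, v, idx[k[1]], level)
}

first_cross_down <- function(t, v, idx, level) {
  rel <- v[idx]
  k <- which(rel[-1] <= level & rel[-length(rel)] > level)
  if (!length(k)) return(NA_real_)
  cross_time(t, v, idx[k[1]], level)
}
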