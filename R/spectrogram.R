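#' Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with a complex Morlet mother wavelet
#' (center frequency parameter `omega0 = 6`), evaluated by FFT convolution.
#' Scales are chosen so that each requested frequency coincides with the
#' wavelet's center frequency, `s = omega0 / (2 * pi * f)`; power is the
#' squared transform magnitude on the signal's own time base. The Morlet
#' wavelet trades time against frequency resolution smoothly, which suits
#' transient epileptiform activity.
#'
#' @param sig an [timeseries()].
#' @param freqs requested analysis frequencies in Hz, all below Nyquist.
#' @param omega0 Morlet center frequency parameter (dimensionless).
#' @return a list of class `eps_cwt`: `power` (matrix, `length(freqs)` rows x
#'   `nrow(sig)` columns), `freqs`, `time_s`.
#' @export
wavelet_spectrogram <- function(sig, freqs, omega0 = 6) {
  validate_timeseries(sig)
  fs <- ts_rate(sig)
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    abort("requested frequency at or above Nyquist")
  }
  x <- sig$value
  n <- length(x)
  xh <- fft(x)
  w <- 2 * pi * fs * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i]) # scale in seconds
    psi <- sqrt(2 * pi * s * fs) * pi^(-0.25) * exp(-0.5 * (s * w - omega0)^2)
    psi[w < 0] <- 0
    wt <- fft(xh * psi, inverse = TRUE) / n
    power[i, ] <- Mod(wt)^2
  }
  structure(list(power = power, freqs = freqs, time_s = sig$time_s),
    class = "eps_cwt"
  )
}
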