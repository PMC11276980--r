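#' Configuration for the synthetic LFP generator
#'
#' Describes 4-AP-like epileptiform activity in a slice LFP recording:
#' background interictal transients from a gamma renewal process, a small
#' number of ictal discharges modeled as dense clusters of the same
#' transients, and additive noise. Amplitudes are expressed relative to the
#' noise standard deviation because slice LFPs carry no absolute calibration
#' (detection is scale-invariant anyway).
#'
#' Defaults reflect the activity regime the detector is designed for:
#' interictal events every 2-4 s (renewal rate 0.4 events/s, gamma shape 4
#' giving a narrow interval mode at the mean), ictal clusters of 30 events
#' at 0.3 s intra-cluster intervals (+/-20% jitter), and transient peaks 8
#' times the noise SD.
#'
#' @param duration recording length, s.
#' @param rate sampling rate, Hz (>= 1000).
#' @param interictal_rate background event rate, events/s (renewal process;
#'   0 disables background events).
#' @param interictal_amplitude transient peak amplitude in units of
#'   `noise_sd`.
#' @param interictal_width duration of the sharp lobe of the biphasic
#'   transient, s; the slower opposite lobe is three times as long with 40%
#'   of the amplitude.
#' @param ictal_cluster_count number of planted ictal clusters.
#' @param intra_cluster_interval nominal interval between cluster events, s;
#'   must exceed the 0.05 s detector lockout.
#' @param cluster_n_events events per cluster.
#' @param noise_sd noise standard deviation, a.u.
#' @param noise_spectrum `"white"` or `"pink+white"` (equal-power mix).
#' @param polarity sign of the sharp lobe, `"positive"` or `"negative"`.
#' @param gamma_shape shape of the gamma renewal interval distribution.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an `lfp_sim_config` list.
#' @export
lfp_sim_config <- function(duration = 600, rate = 10000,
                           interictal_rate = 0.4, interictal_amplitude = 8,
                           interictal_width = 0.01, ictal_cluster_count = 3L,
                           intra_cluster_interval = 0.3,
                           cluster_n_events = 30L, noise_sd = 1,
                           noise_spectrum = c("white", "pink+white"),
                           polarity = c("positive", "negative"),
                           gamma_shape = 4, seed = NULL) {
  noise_spectrum <- match.arg(noise_spectrum)
  polarity <- match.arg(polarity)
  if (duration <= 0) abort("duration must be > 0")
  if (rate < 1000) abort("rate must be >= 1000 Hz")
  if (interictal_rate < 0) abort("interictal_rate must be >= 0")
  if (intra_cluster_interval <= 0.05) {
    abort("intra_cluster_interval must exceed the 0.05 s lockout")
  }
  structure(
    list(
      duration = duration, rate = rate, interictal_rate = interictal_rate,
      interictal_amplitude = interictal_amplitude,
      interictal_width = interictal_width,
      ictal_cluster_count = as.integer(ictal_cluster_count),
      intra_cluster_interval = intra_cluster_interval,
      cluster_n_events = as.integer(cluster_n_events),
      noise_sd = noise_sd, noise_spectrum = noise_spectrum,
      polarity = polarity, gamma_shape = gamma_shape, seed = seed
    ),
    class = "lfp_sim_config"
  )
}

# biphasic transient: sharp sin^2 lobe of width w1, then an opposite lobe of
# width 3*w1 at 40% amplitude; peak amplitude = amp, onset at sample 1
transient_wave <- function(amp, w1, rate, sign = 1) {
  n1 <- max(2L, round(w1 * rate))
  n2 <- max(2L, round(3 * w1 * rate))
  lobe1 <- amp * sin(pi * seq(0, 1, length.out = n1))^2
  lobe2 <- -0.4 * amp * sin(pi * seq(0, 1, length.out = n2))^2
  sign * c(lobe1, lobe2)
}

#' Simulate a 4-AP-like LFP recording with planted ground truth
#'
#' Generates interictal onsets from a gamma renewal process (minimum
#' interval 0.1 s), places the configured number of ictal clusters (runs of
#' `cluster_n_events` events at `intra_cluster_interval` with +/-20% uniform
#' jitter) without overlap, superimposes a biphasic transient at every
#' onset, and adds noise. The renewal process is generated on a background
#' time axis that excludes the cluster spans (plus a 0.3 s guard) and is
#' mapped back into real time, i.e. the process pauses during clusters;
#' this preserves the planted interval distribution instead of biasing it
#' by deletion. Identical configuration and seed give bit-identical output.
#'
#' @param cfg an [lfp_sim_config()].
#' @return a list: `lfp` (an [timeseries()]), `events` (ground-truth
#'   [event_train()]), `classes` (per-event `"interictal"` /
#'   `"ictal-member"`), `discharges` (ground-truth cluster spans:
#'   `start_s`, `end_s`, `n_uees`, `member_times`).
#' @export
simulate_lfp <- function(cfg = lfp_sim_config()) {
  stopifnot(inherits(cfg, "lfp_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dur <- cfg$duration

  # ictal clusters first: their spans constrain everything else
  clusters <- list()
  if (cfg$ictal_cluster_count > 0L) {
    spans <- matrix(numeric(0), ncol = 2)
    margin <- 2
    for (k in seq_len(cfg$ictal_cluster_count)) {
      gaps <- cfg$intra_cluster_interval *
        (1 + runif(cfg$cluster_n_events - 1L, -0.2, 0.2))
      cdur <- sum(gaps)
      if (dur - cdur - 2 * margin <= 0) abort("duration too short")
      placed <- FALSE
      for (try in seq_len(2000L)) {
        start <- runif(1, margin, dur - cdur - margin)
        ok <- !nrow(spans) ||
          all(start > spans[, 2] + 5 | start + cdur < spans[, 1] - 5)
        if (ok) {
          spans <- rbind(spans, c(start, start + cdur))
          clusters[[k]] <- start + c(0, cumsum(gaps))
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("duration too short")
    }
  }
  cluster_times <- unlist(clusters)

  # interictal background: gamma renewal generated on "background time"
  # that excludes the cluster spans (plus a 0.3 s guard), then mapped back
  # into real time - pausing the process during clusters rather than
  # deleting events keeps the planted interval distribution intact
  inter <- numeric(0)
  if (cfg$interictal_rate > 0) {
    guard <- 0.3
    spans <- purrr::map_dfr(clusters, function(cl) {
      tibble(start = min(cl) - guard, end = max(cl) + guard)
    })
    if (nrow(spans)) spans <- dplyr::arrange(spans, .data$start)
    span_len <- if (nrow(spans)) spans$end - spans$start else numeric(0)
    bg_dur <- dur - sum(span_len)
    n_draw <- ceiling(bg_dur * cfg$interictal_rate * 2 + 50)
    repeat {
      iv <- pmax(0.1, rgamma(n_draw,
        shape = cfg$gamma_shape,
        rate = cfg$gamma_shape * cfg$interictal_rate
      ))
      tt <- cumsum(iv)
      if (tt[length(tt)] > bg_dur) break
      n_draw <- n_draw * 2L
    }
    tt <- tt[tt < bg_dur - 0.2]
    if (nrow(spans)) {
      # background coordinate of each span start; events past the i-th
      # break are shifted right by the total span length removed so far
      breaks <- spans$start - c(0, cumsum(span_len))[seq_len(nrow(spans))]
      idx <- findInterval(tt, breaks)
      tt <- tt + c(0, cumsum(span_len))[idx + 1L]
    }
    inter <- tt[tt < dur - 0.2]
  }

  times <- sort(c(inter, cluster_times))
  classes <- rep("interictal", length(times))
  classes[times %in% cluster_times] <- "ictal-member"

  # assemble the signal
  n <- round(dur * cfg$rate)
  amp <- cfg$interictal_amplitude * cfg$noise_sd
  sgn <- if (cfg$polarity == "positive") 1 else -1
  wave <- transient_wave(amp, cfg$interictal_width, cfg$rate, sgn)
  x <- numeric(n)
  nw <- length(wave)
  for (t in times) {
    i0 <- round(t * cfg$rate) + 1L
    i1 <- min(n, i0 + nw - 1L)
    if (i0 <= n) x[i0:i1] <- x[i0:i1] + wave[seq_len(i1 - i0 + 1L)]
  }
  x <- x + gen_noise(n, cfg$noise_sd, cfg$noise_spectrum)

  discharges <- purrr::map_dfr(clusters, function(cl) {
    tibble(
      start_s = cl[1], end_s = cl[length(cl)], n_uees = length(cl),
      member_times = list(cl)
    )
  })
  if (!nrow(discharges)) {
    discharges <- tibble(
      start_s = numeric(), end_s = numeric(), n_uees = integer(),
      member_times = list()
    )
  }
  discharges <- dplyr::arrange(discharges, .data$start_s)
  validate_discharges(discharges)

  list(
    lfp = timeseries(x, rate = cfg$rate, units = "a.u.", label = "lfp"),
    events = event_train(times, duration = dur, lockout = 0.05),
    classes = classes,
    discharges = discharges
  )
}

gen_noise <- function(n, sd, spectrum) {
  if (sd <= 0) return(numeric(n))
  white <- rnorm(n, 0, sd)
  if (spectrum == "white") return(white)
  # pink component by 1/f spectral shaping, mixed at equal power
  w <- rnorm(n)
  wh <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index
  shaped <- Re(fft(wh / sqrt(f), inverse = TRUE)) / n
  pink <- shaped / sd(shaped)
  (white + pink * sd) / sqrt(2)
}
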