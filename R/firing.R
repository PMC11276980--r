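#' Firing-pattern metrics from a current-step family
#'
#' Builds the current-frequency (f-I) relationship (spike count divided by
#' step duration per sweep) and derives: rheobase (smallest current
#' eliciting at least one AP); time of the first spike at rheobase
#' (measured from step onset to the first AP threshold); maximum firing
#' rate and the smallest current attaining it; the depolarizing-block
#' current (smallest current above `current_at_max` whose rate falls below
#' half the maximum while the membrane sits at a sustained depolarized
#' plateau - mean voltage over the last third of the step above the AP
#' threshold minus 5 mV); the maximum slope of the f-I curve on its rising
#' limb; and the early and late frequency-adaptation ratios (second and
#' last inter-spike interval over the first) measured on the first sweep
#' above rheobase, which needs at least 3 spikes.
#'
#' @param family an [sweep_family()].
#' @param dvdt_threshold AP detection slope threshold, mV/ms.
#' @param block_rate_fraction rate-drop fraction defining depolarizing
#'   block.
#' @param plateau_margin_mv plateau criterion margin below AP threshold.
#' @return object of class `firing_pattern`: a list with `rheobase`,
#'   `time_of_first_spike` (ms), `fi_curve` (tibble `current_pa`,
#'   `rate_hz`), `max_rate`, `current_at_max`, `block_current`,
#'   `max_fi_slope` (Hz/pA), `early_adaptation`, `late_adaptation` and the
#'   per-sweep spike trains.
#' @export
firing_pattern <- function(family, dvdt_threshold = 5,
                           block_rate_fraction = 0.5, plateau_margin_mv = 5) {
  stopifnot(inherits(family, "eps_sweeps"))
  proto <- family_protocol(family)
  fs <- family_rate(family)
  amps <- proto$amplitudes
  i_on <- round(proto$step_onset * fs)
  i_off <- i_on + round(proto$step_duration * fs)

  sweeps <- lapply(seq_along(amps), function(i) family_sweep(family, i))
  trains <- lapply(sweeps, detect_spikes, dvdt_threshold = dvdt_threshold)
  counts <- vapply(trains, nrow, integer(1))
  fi <- tibble(
    current_pa = amps, rate_hz = counts / proto$step_duration
  )

  spiking <- which(counts > 0L)
  if (!length(spiking)) abort("no rheobase")
  i_rheo <- spiking[which.min(amps[spiking])]
  rheobase <- amps[i_rheo]
  t_first <- 1000 * (trains[[i_rheo]]$t_thr[1] - proto$step_onset)

  max_rate <- max(fi$rate_hz)
  i_max <- which(fi$rate_hz == max_rate)
  i_max <- i_max[which.min(amps[i_max])]
  current_at_max <- amps[i_max]

  # representative AP threshold for the plateau criterion
  thr_v <- median(unlist(lapply(spiking, function(i) {
    vapply(trains[[i]]$t_thr, function(tt) {
      sweeps[[i]]$value[which.min(abs(sweeps[[i]]$time_s - tt))]
    }, numeric(1))
  })))

  block_current <- NA_real_
  cand <- which(amps > current_at_max &
    fi$rate_hz < block_rate_fraction * max_rate)
  for (i in cand[order(amps[cand])]) {
    seg <- (i_off - round((i_off - i_on) / 3)):i_off
    if (mean(sweeps[[i]]$value[seg]) > thr_v - plateau_margin_mv) {
      block_current <- amps[i]
      break
    }
  }

  rising <- which(amps <= current_at_max)
  ord <- rising[order(amps[rising])]
  max_fi_slope <- if (length(ord) > 1L) {
    max(diff(fi$rate_hz[ord]) / diff(amps[ord]))
  } else {
    NA_real_
  }

  early <- late <- NA_real_
  above <- which(amps > rheobase & counts >= 3L)
  if (length(above)) {
    i_ad <- above[which.min(amps[above])]
    # only use the immediately next amplitude above rheobase
    next_amp <- min(amps[amps > rheobase])
    if (abs(amps[i_ad] - next_amp) < 1e-9) {
      isi <- diff(trains[[i_ad]]$t_thr)
      early <- isi[2] / isi[1]
      late <- isi[length(isi)] / isi[1]
    }
  }

  structure(
    list(
      rheobase = rheobase, time_of_first_spike = t_first, fi_curve = fi,
      max_rate = max_rate, current_at_max = current_at_max,
      block_current = block_current, max_fi_slope = max_fi_slope,
      early_adaptation = early, late_adaptation = late,
      spike_trains = trains, ap_threshold_v = thr_v
    ),
    class = "firing_pattern"
  )
}

#' @export
print.firing_pattern <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Firing pattern\n  rheobase: %g pA\n  first spike: %.1f ms\n",
      "  max rate: %.2f Hz at %g pA\n  block current: %s pA\n",
      "  max f-I slope: %.3f Hz/pA\n  adaptation early/late: %.3f / %.3f\n"
    ),
    x$rheobase, x$time_of_first_spike, x$max_rate, x$current_at_max,
    format(x$block_current), x$max_fi_slope, x$early_adaptation,
    x$late_adaptation
  ))
  invisible(x)
}
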