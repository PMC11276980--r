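#' Configuration for the synthetic evoked-EPSC generator
#'
#' Parameters of simulated evoked excitatory postsynaptic currents under
#' voltage clamp: each stimulus elicits an instantaneous-rise,
#' exponential-decay inward current whose peak is `a1` scaled by a per-pulse
#' gain, superposed on the decaying tails of earlier responses.
#'
#' @param a1 first-response peak amplitude, pA (> 0).
#' @param ppr paired-pulse ratio (gain of the second pulse in 2-pulse
#'   protocols).
#' @param per_pulse_ratio gains of the 5 pulses in train protocols; the
#'   first must be 1.
#' @param decay_tau EPSC decay time constant, ms.
#' @param isi inter-stimulus interval, s (0.05 s = 50 Hz trains and the
#'   standard paired-pulse spacing).
#' @param noise_sd additive white noise SD, pA.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a `syn_sim_config` list.
#' @export
syn_sim_config <- function(a1 = 100, ppr = 1.5,
                           per_pulse_ratio = c(1, 1.5, 1.8, 2.0, 2.1),
                           decay_tau = 20, isi = 0.05, noise_sd = 1,
                           seed = NULL) {
  if (a1 <= 0) abort("a1 must be > 0")
  if (length(per_pulse_ratio) != 5L || abs(per_pulse_ratio[1] - 1) > 1e-12) {
    abort("per_pulse_ratio must have 5 entries with first entry 1")
  }
  if (isi <= 0) abort("isi must be > 0")
  if (decay_tau <= 0) abort("decay_tau must be > 0")
  structure(
    list(
      a1 = a1, ppr = ppr, per_pulse_ratio = per_pulse_ratio,
      decay_tau = decay_tau, isi = isi, noise_sd = noise_sd, seed = seed
    ),
    class = "syn_sim_config"
  )
}

#' Simulate paired-pulse or train EPSCs with planted ground truth
#'
#' Builds a voltage-clamp current trace in which each of `n_pulses` stimuli
#' elicits an inward (negative) current of peak `a1 * gain_k` with
#' instantaneous rise and exponential decay, added to the superposed tail of
#' the previous responses. For 2-pulse protocols the second gain is
#' `cfg$ppr`; 5-pulse trains use `cfg$per_pulse_ratio`. The ground truth
#' stores both the isolated peak of each response and the closed-form
#' superposed trace magnitude at each stimulus peak,
#' `sum_j A_j * exp(-(t_k - t_j) / tau)`.
#'
#' @param cfg a [syn_sim_config()].
#' @param n_pulses 2 (paired pulse) or 5 (train).
#' @param rate sampling rate, Hz.
#' @param pathway label passed through to the stimulus markers.
#' @return a list: `trace` (an [timeseries()], pA), `stims`
#'   ([stim_markers()]) and `truth` (tibble `pulse`, `isolated_pa`,
#'   `superposed_pa`).
#' @export
simulate_epsc_trains <- function(cfg = syn_sim_config(), n_pulses = 2L,
                                 rate = 20000,
                                 pathway = c("other", "schaffer", "temporoammonic")) {
  stopifnot(inherits(cfg, "syn_sim_config"))
  pathway <- match.arg(pathway)
  if (!n_pulses %in% c(2L, 5L)) abort("n_pulses must be 2 or 5")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gains <- if (n_pulses == 2L) c(1, cfg$ppr) else cfg$per_pulse_ratio
  amps <- cfg$a1 * gains
  tau <- cfg$decay_tau / 1000
  stim_t <- 0.1 + (seq_len(n_pulses) - 1) * cfg$isi
  dur <- 0.1 + (n_pulses - 1) * cfg$isi + 0.3
  n <- round(dur * rate)
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (k in seq_len(n_pulses)) {
    on <- t >= stim_t[k]
    x[on] <- x[on] - amps[k] * exp(-(t[on] - stim_t[k]) / tau)
  }
  if (cfg$noise_sd > 0) x <- x + rnorm(n, 0, cfg$noise_sd)
  superposed <- vapply(seq_len(n_pulses), function(k) {
    sum(amps[seq_len(k)] * exp(-(stim_t[k] - stim_t[seq_len(k)]) / tau))
  }, numeric(1))
  list(
    trace = timeseries(x, rate = rate, units = "pA", label = "epsc"),
    stims = stim_markers(stim_t, pathway = pathway),
    truth = tibble(
      pulse = seq_len(n_pulses), isolated_pa = amps, superposed_pa = superposed
    )
  )
}
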