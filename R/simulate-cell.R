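#' Configuration for the synthetic current-clamp generator
#'
#' Ground-truth membrane and action-potential parameters of a simulated
#' cell. Defaults sit in the range typical of CA1 pyramidal neurons:
#' resting potential about -63 mV, input resistance about 90 MOhm, membrane
#' time constant about 20 ms, AP threshold about -44 mV with 100 mV
#' amplitude, fast and medium afterhyperpolarizations of -6 and -10 mV
#' relative to threshold, and a 2 mV afterdepolarization between them.
#'
#' The cell is a leaky integrate-and-fire membrane with spike-triggered
#' adaptation. `rheobase` is planted directly: the dynamical initiation
#' threshold is set to `rmp + 0.98 * rheobase * r_in`, so sweeps at or above
#' the planted rheobase spike and sweeps below it do not. `spike_threshold`
#' is the AP voltage threshold built into the stereotyped waveform (its foot
#' reaches a 5 mV/ms rise exactly at that voltage). Above `block_current`
#' spiking ceases 200 ms into the step and the membrane sits at a
#' depolarized plateau (depolarizing block, modeled phenomenologically).
#' Membrane dynamics are deterministic; noise is observational, an
#' Ornstein-Uhlenbeck process (2 ms correlation time, matching
#' amplifier/membrane filtering) added to the finished trace.
#'
#' @param rmp resting membrane potential, mV.
#' @param r_in input resistance, MOhm.
#' @param tau_m membrane time constant, ms.
#' @param spike_threshold AP voltage threshold, mV.
#' @param spike_amplitude AP peak relative to threshold, mV.
#' @param fahp_depth fast AHP relative to threshold, mV (negative).
#' @param mahp_depth medium AHP relative to threshold, mV (negative, deeper
#'   than `fahp_depth`).
#' @param adp_amplitude afterdepolarization above the fAHP trough, mV.
#' @param rheobase planted rheobase current, pA; choose a value on the
#'   protocol's amplitude grid.
#' @param adaptation_strength spike-triggered adaptation increment in units
#'   of 50 pA; 0 gives perfectly regular firing.
#' @param block_current depolarizing-block current, pA (> rheobase).
#' @param noise_sd observational noise SD, mV.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a `cell_sim_config` list.
#' @export
cell_sim_config <- function(rmp = -63, r_in = 90, tau_m = 20,
                            spike_threshold = -44, spike_amplitude = 100,
                            fahp_depth = -6, mahp_depth = -10,
                            adp_amplitude = 2, rheobase = 160,
                            adaptation_strength = 0.3, block_current = 500,
                            noise_sd = 0.2, seed = NULL) {
  if (tau_m <= 0) abort("tau_m must be > 0")
  if (r_in <= 0) abort("r_in must be > 0")
  if (block_current <= rheobase) abort("block_current must exceed rheobase")
  if (mahp_depth >= fahp_depth) abort("mahp_depth must be below fahp_depth")
  structure(
    list(
      rmp = rmp, r_in = r_in, tau_m = tau_m,
      spike_threshold = spike_threshold, spike_amplitude = spike_amplitude,
      fahp_depth = fahp_depth, mahp_depth = mahp_depth,
      adp_amplitude = adp_amplitude, rheobase = rheobase,
      adaptation_strength = adaptation_strength,
      block_current = block_current, noise_sd = noise_sd, seed = seed
    ),
    class = "cell_sim_config"
  )
}

# Stereotyped AP waveform sampled at dt_ms, starting at the initiation
# threshold theta_eff: a two-phase foot (slow rise with slope capped at
# 2.5 mV/ms, then a 1 ms acceleration whose slope reaches 5 mV/ms exactly
# at the AP voltage threshold - keeping the dV/dt detection criterion
# sharply localized even when theta_eff sits far below the threshold),
# half-cosine upstroke (0.6 ms) and repolarization (2.0 ms) to the fAHP,
# half-sine ADP bump (8 ms), half-cosine descent to the mAHP trough
# (32 ms). Returns the samples plus closed-form feature values implied by
# the geometry.
ap_waveform <- function(cfg, theta_eff, dt_ms) {
  thr <- cfg$spike_threshold
  amp <- cfg$spike_amplitude
  vf <- thr + cfg$fahp_depth
  vm <- thr + cfg$mahp_depth
  d_up <- 0.6
  d_down <- 2.0
  d_adp <- 8
  d_m <- 32
  seg <- function(d) seq(dt_ms, d, by = dt_ms)
  gap <- thr - theta_eff
  if (gap <= 3.75) {
    # short approach: single quadratic, slope 0 -> 5 mV/ms, ending at thr
    d_foot <- max(2 * dt_ms, gap / 2.5)
    foot <- theta_eff + 2.5 * seg(d_foot)^2 / d_foot
  } else {
    # phase A: slope ramps 0 -> 2.5 mV/ms (rise gap - 3.75 mV);
    # phase B (1 ms): slope ramps 2.5 -> 5 mV/ms (rise 3.75 mV)
    d_a <- max(2 * dt_ms, (gap - 3.75) / 1.25)
    v1 <- thr - 3.75
    foot_a <- theta_eff + 1.25 * seg(d_a)^2 / d_a
    s <- seg(1)
    foot_b <- v1 + 2.5 * s + 1.25 * s^2
    foot <- c(foot_a, foot_b)
  }
  up <- thr + amp * (1 - cos(pi * seg(d_up) / d_up)) / 2
  down <- (thr + amp) - (amp - cfg$fahp_depth) *
    (1 - cos(pi * seg(d_down) / d_down)) / 2
  adp <- vf + cfg$adp_amplitude * sin(pi * seg(d_adp) / d_adp)
  mdown <- vf - (vf - vm) * (1 - cos(pi * seg(d_m) / d_m)) / 2
  wave <- c(theta_eff, foot, up, down, adp, mdown)
  t_thr_ms <- length(foot) * dt_ms # threshold time within the waveform
  features <- tibble(
    threshold_v = thr,
    amplitude = amp,
    rise_10_90 = d_up * (acos(1 - 1.8) - acos(1 - 0.2)) / pi,
    half_width = d_up / 2 + d_down * acos(1 - amp / (amp - cfg$fahp_depth)) / pi,
    fahp = cfg$fahp_depth,
    mahp = cfg$mahp_depth,
    time_to_mahp = d_adp + d_m,
    adp = cfg$adp_amplitude
  )
  list(wave = wave, t_thr_ms = t_thr_ms, features = features,
       v_resume = vm)
}

#' Simulate a current-step sweep family with planted ground truth
#'
#' Runs the integrate-and-fire cell described by `cfg` through every
#' amplitude of `protocol`. Subthreshold responses are single-exponential RC
#' charging toward `rmp + I * r_in`; at and above the planted rheobase,
#' spikes are emitted wherever the (deterministic) membrane crosses the
#' initiation threshold and the stereotyped AP waveform is pasted in, with
#' inter-spike intervals lengthening according to `adaptation_strength`;
#' at and above `block_current` spiking ceases 200 ms into the step.
#' Observational noise is added last.
#'
#' @param cfg a [cell_sim_config()].
#' @param protocol a [step_protocol()].
#' @param rate sampling rate, Hz.
#' @return a list: `family` (an [sweep_family()]) and `truth`, which
#'   records the planted parameters (`params`, including the closed-form AP
#'   waveform features), per-sweep AP threshold times (`spikes`), the
#'   spike-count rate table (`fi`), and the planted `rheobase`.
#' @export
simulate_current_steps <- function(cfg = cell_sim_config(),
                                   protocol = step_protocol(),
                                   rate = 25000) {
  stopifnot(inherits(cfg, "cell_sim_config"), inherits(protocol, "step_protocol"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  amps <- protocol$amplitudes
  if (cfg$rheobase > max(amps) || cfg$rheobase < min(amps)) {
    warn("planted rheobase lies outside the protocol amplitude range")
  }
  theta_eff <- cfg$rmp + 0.98 * cfg$rheobase * cfg$r_in * 1e-3
  if (theta_eff >= cfg$spike_threshold) {
    warn("initiation threshold at or above spike_threshold; clamping")
    theta_eff <- cfg$spike_threshold - 0.5
  }
  dt <- 1 / rate
  dt_ms <- 1000 * dt
  wf <- ap_waveform(cfg, theta_eff, dt_ms)
  n_wave <- length(wf$wave)

  sweep_dur <- protocol$step_onset + protocol$step_duration + 0.5
  n <- round(sweep_dur * rate)
  i_on <- round(protocol$step_onset * rate)
  i_off <- i_on + round(protocol$step_duration * rate)

  sweeps <- vector("list", length(amps))
  spike_rows <- vector("list", length(amps))
  for (k in seq_along(amps)) {
    I <- amps[k]
    theta <- if (I >= cfg$rheobase - 1e-9) theta_eff else NA_real_
    res <- iaf_integrate_cpp(
      n, dt, cfg$rmp, I, cfg$r_in, cfg$tau_m, 400, theta, i_on, i_off,
      w_jump = cfg$adaptation_strength * 50, n_wave = n_wave,
      v_resume = wf$v_resume, blocked = I >= cfg$block_current - 1e-9,
      block_t = 0.2, v_plateau = cfg$spike_threshold + 5
    )
    v <- res$v
    for (i0 in res$spike_idx) {
      idx <- (i0 + 1L):min(n, i0 + n_wave)
      v[idx] <- wf$wave[seq_along(idx)]
    }
    t_thr <- res$spike_idx * dt + wf$t_thr_ms / 1000
    spike_rows[[k]] <- tibble(
      sweep = k, amplitude_pa = I, n_spikes = length(t_thr),
      t_thr = list(t_thr)
    )
    if (cfg$noise_sd > 0) {
      rho <- exp(-dt / 0.002)
      eps <- rnorm(n, 0, cfg$noise_sd * sqrt(1 - rho^2))
      eps[1] <- rnorm(1, 0, cfg$noise_sd)
      v <- v + as.numeric(stats::filter(eps, rho, method = "recursive"))
    }
    sweeps[[k]] <- timeseries(v, rate = rate, units = "mV",
                              label = paste0("sweep", k))
  }
  spikes <- dplyr::bind_rows(spike_rows)
  fi <- dplyr::mutate(spikes, rate_hz = .data$n_spikes / protocol$step_duration)

  list(
    family = sweep_family(sweeps, protocol),
    truth = list(
      params = tibble(
        rmp = cfg$rmp, r_in = cfg$r_in, tau_m = cfg$tau_m,
        rheobase = cfg$rheobase, block_current = cfg$block_current
      ),
      ap = wf$features,
      spikes = spikes,
      fi = fi[, c("amplitude_pa", "n_spikes", "rate_hz")],
      theta_eff = theta_eff
    )
  )
}
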