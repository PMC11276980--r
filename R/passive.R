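#' Estimate passive membrane properties from a current-step family
#'
#' Resting membrane potential is the mean pre-step voltage of the
#' zero-current sweep (or of all spike-free sweeps when no zero-current
#' sweep exists). Input resistance is the slope of an ordinary
#' least-squares regression of the steady-state voltage deflection (mean
#' over the last 20% of the step) on injected current, restricted to
#' spike-free sweeps. The membrane time constant is obtained by nonlinear
#' least-squares fit of a single exponential
#' `V(t) = Vinf + (V0 - Vinf) * exp(-t / tau)` to the onset of the response
#' to the largest hyperpolarizing step (fit window: step onset to five times
#' an initial log-linear estimate of tau).
#'
#' @param family an [sweep_family()].
#' @param dvdt_threshold slope threshold used to discard sweeps containing
#'   spikes, mV/ms.
#' @return object of class `passive_properties`: a list with `rmp` (mV),
#'   `r_in` (MOhm), `tau_m` (ms), the per-sweep current-voltage table `iv`
#'   and the tau fit object.
#' @export
estimate_passive <- function(family, dvdt_threshold = 5) {
  stopifnot(inherits(family, "eps_sweeps"))
  proto <- family_protocol(family)
  fs <- family_rate(family)
  amps <- proto$amplitudes
  i_on <- round(proto$step_onset * fs)
  i_off <- i_on + round(proto$step_duration * fs)
  n_ss <- round(0.2 * (i_off - i_on)) # last 20% of the step

  sweeps <- lapply(seq_along(amps), function(i) family_sweep(family, i))
  has_spikes <- vapply(sweeps, function(s) {
    nrow(detect_spikes(s, dvdt_threshold)) > 0L
  }, logical(1))
  sub <- which(!has_spikes)
  if (length(sub) < 3L) abort("insufficient subthreshold data")
  if (!any(amps[sub] < 0)) abort("insufficient subthreshold data")

  base_mean <- vapply(sweeps, function(s) mean(s$value[seq_len(i_on)]), numeric(1))
  ss_mean <- vapply(sweeps, function(s) {
    mean(s$value[(i_off - n_ss + 1L):i_off])
  }, numeric(1))

  i_zero <- which(abs(amps) < 1e-9)
  rmp <- if (length(i_zero)) base_mean[i_zero[1]] else mean(base_mean[sub])

  iv <- tibble(
    amplitude_pa = amps[sub],
    deflection_mv = ss_mean[sub] - base_mean[sub]
  )
  fit_iv <- lm(deflection_mv ~ amplitude_pa, data = iv)
  r_in <- unname(coef(fit_iv)[2]) * 1000 # mV/pA -> MOhm

  # tau from the largest hyperpolarizing spike-free sweep
  i_hyp <- sub[which.min(amps[sub])]
  sw <- sweeps[[i_hyp]]
  v <- sw$value
  v0 <- base_mean[i_hyp]
  vinf <- ss_mean[i_hyp]
  seg_full <- (i_on + 1L):i_off
  t_rel <- (seg_full - i_on - 1L) / fs
  dv <- v[seg_full] - vinf
  # initial estimate by log-linear regression over the early decay
  usable <- which(sign(dv) == sign(v0 - vinf) & abs(dv) > 0.05 * abs(v0 - vinf))
  usable <- usable[seq_len(min(length(usable), round(0.2 * fs)))]
  if (length(usable) < 5L) abort("tau fit failed")
  lfit <- lm(log(abs(dv[usable])) ~ t_rel[usable])
  tau0 <- -1 / unname(coef(lfit)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- 0.02
  i_fit <- which(t_rel <= 5 * tau0)
  dat <- data.frame(t = t_rel[i_fit], v = v[seg_full][i_fit])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vinf_p + (v0_p - vinf_p) * exp(-t / tau_p),
      data = dat,
      start = list(vinf_p = vinf, v0_p = v0, tau_p = tau0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8)
    ),
    error = function(e) abort("tau fit failed")
  )
  tau_m <- unname(coef(fit)["tau_p"]) * 1000

  structure(
    list(rmp = rmp, r_in = r_in, tau_m = tau_m, iv = iv, tau_fit = fit),
    class = "passive_properties"
  )
}

#' @export
print.passive_properties <- function(x, ...) {
  cat(sprintf(
    "Passive membrane properties\n  RMP: %.2f mV\n  Rin: %.1f MOhm\n  tau_m: %.2f ms\n",
    x$rmp, x$r_in, x$tau_m
  ))
  invisible(x)
}
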