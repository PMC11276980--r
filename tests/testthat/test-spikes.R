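sim_one_sweep <- function(cfg, amp = 200, rate = 25000) {
  p <- step_protocol(amplitudes = c(0, amp))
  sim <- simulate_current_steps(cfg, p, rate = rate)
  list(
    sweep = timeseries(sim$family$v_mv[sim$family$sweep == 2], rate = rate,
                       units = "mV"),
    truth = sim$truth
  )
}

test_that("detect_spikes recovers planted spike times", {
  s <- sim_one_sweep(cell_sim_config(seed = 21))
  det <- detect_spikes(s$sweep)
  planted <- s$truth$spikes$t_thr[[2]]
  expect_equal(nrow(det), length(planted))
  expect_true(all(abs(det$t_thr - planted) < 0.001))
})

test_that("detect_spikes ignores subthreshold depolarization", {
  cfg <- cell_sim_config(seed = 4)
  p <- step_protocol(amplitudes = c(100)) # below rheobase 160
  sim <- suppressWarnings(simulate_current_steps(cfg, p, rate = 25000))
  sweep <- timeseries(sim$family$v_mv, rate = 25000, units = "mV")
  expect_equal(nrow(detect_spikes(sweep)), 0)
})

test_that("ap_features matches the closed-form waveform geometry", {
  cfg <- cell_sim_config(noise_sd = 0)
  s <- sim_one_sweep(cfg, amp = 180)
  det <- detect_spikes(s$sweep)
  truth <- s$truth$ap # closed-form features of the stereotyped waveform
  f <- ap_features(s$sweep, det$t_thr[1], next_onset = det$t_thr[2])
  expect_s3_class(f, "eps_apf")
  expect_equal(f$threshold_v, truth$threshold_v, tolerance = 0.02)
  expect_equal(f$amplitude, truth$amplitude, tolerance = 0.02)
  expect_equal(f$rise_10_90, truth$rise_10_90, tolerance = 0.05)
  expect_equal(f$half_width, truth$half_width, tolerance = 0.05)
  expect_equal(f$fahp, truth$fahp, tolerance = 0.1)
  expect_equal(f$mahp, truth$mahp, tolerance = 0.05)
  expect_equal(f$time_to_mahp, truth$time_to_mahp, tolerance = 0.05)
  expect_equal(f$adp, truth$adp, tolerance = 0.1)
})

test_that("a truncated window yields NAs with a warning, not guesses", {
  cfg <- cell_sim_config(noise_sd = 0)
  s <- sim_one_sweep(cfg, amp = 180)
  det <- detect_spikes(s$sweep)
  # a 15 ms window ends during the descent to the mAHP trough
  expect_warning(
    f <- ap_features(s$sweep, det$t_thr[1],
                     next_onset = det$t_thr[1] + 0.015),
    "incomplete AHP window"
  )
  expect_true(is.na(f$mahp))
  expect_true(is.na(f$time_to_mahp))
})

test_that("spike features are stable under observational noise", {
  s <- sim_one_sweep(cell_sim_config(seed = 77), amp = 180)
  det <- detect_spikes(s$sweep)
  truth <- s$truth$ap
  f <- ap_features(s$sweep, det$t_thr[1], next_onset = det$t_thr[2])
  expect_lt(relerr(f$amplitude, truth$amplitude), 0.05)
  expect_lt(relerr(f$half_width, truth$half_width), 0.10)
})
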