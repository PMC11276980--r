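test_that("simulate_current_steps is deterministic given a seed", {
  p <- step_protocol(amplitudes = seq(-100, 300, by = 50))
  a <- simulate_current_steps(cell_sim_config(seed = 7), p, rate = 10000)
  b <- simulate_current_steps(cell_sim_config(seed = 7), p, rate = 10000)
  expect_identical(a$family$v_mv, b$family$v_mv)
  expect_identical(a$truth$spikes$n_spikes, b$truth$spikes$n_spikes)
})

test_that("the planted rheobase separates spiking from silent sweeps", {
  cfg <- cell_sim_config(rheobase = 160, seed = 1)
  sim <- simulate_current_steps(cfg, step_protocol(), rate = 10000)
  sp <- sim$truth$spikes
  expect_true(all(sp$n_spikes[sp$amplitude_pa < 160] == 0))
  expect_true(all(sp$n_spikes[sp$amplitude_pa >= 160 &
                              sp$amplitude_pa < cfg$block_current] >= 1))
})

test_that("subthreshold sweeps follow RC charging toward rmp + I * Rin", {
  cfg <- cell_sim_config(noise_sd = 0, seed = NULL)
  p <- step_protocol(amplitudes = c(-100, -50, 0, 50))
  sim <- suppressWarnings(simulate_current_steps(cfg, p, rate = 10000))
  for (k in 1:4) {
    v <- sim$family$v_mv[sim$family$sweep == k]
    i_pa <- p$amplitudes[k]
    # steady state at the end of the 1.5 s step (75 tau_m)
    i_end <- round((p$step_onset + p$step_duration) * 10000)
    expect_equal(v[i_end - 10], cfg$rmp + i_pa * cfg$r_in * 1e-3,
                 tolerance = 1e-6)
    # baseline at rest
    expect_equal(v[10], cfg$rmp, tolerance = 1e-9)
  }
})

test_that("depolarizing block silences spiking after 200 ms", {
  cfg <- cell_sim_config(block_current = 400, seed = 2)
  sim <- simulate_current_steps(cfg, step_protocol(), rate = 10000)
  sp <- sim$truth$spikes
  blocked <- which(sp$amplitude_pa >= 400)
  for (i in blocked) {
    tt <- sp$t_thr[[i]]
    expect_true(all(tt <= 0.25 + 0.2 + 0.01)) # onset + 200 ms
  }
  # and the membrane sits at a depolarized plateau late in the step
  k <- blocked[1]
  v <- sim$family$v_mv[sim$family$sweep == k]
  late <- v[round(1.2 * 10000):round(1.7 * 10000)]
  expect_gt(mean(late), cfg$spike_threshold - 2)
})

test_that("adaptation lengthens inter-spike intervals", {
  p <- step_protocol(amplitudes = c(0, 200))
  ad <- simulate_current_steps(
    cell_sim_config(adaptation_strength = 0.5, noise_sd = 0), p, rate = 10000
  )
  isi <- diff(ad$truth$spikes$t_thr[[2]])
  expect_gt(length(isi), 2)
  expect_true(all(diff(isi) >= -1e-9)) # non-decreasing ISIs
  expect_gt(isi[length(isi)], isi[1])
  none <- simulate_current_steps(
    cell_sim_config(adaptation_strength = 0, noise_sd = 0), p, rate = 10000
  )
  isi0 <- diff(none$truth$spikes$t_thr[[2]])
  expect_equal(diff(range(isi0)), 0) # perfectly regular
})

test_that("configuration validation catches inconsistent cells", {
  expect_error(cell_sim_config(block_current = 100, rheobase = 160),
               "block_current")
  expect_error(cell_sim_config(mahp_depth = -3, fahp_depth = -6), "mahp")
  expect_error(cell_sim_config(tau_m = 0), "tau_m")
  expect_warning(
    simulate_current_steps(
      cell_sim_config(rheobase = 700, block_current = 800, r_in = 20),
      step_protocol(amplitudes = seq(-100, 600, by = 100)), rate = 5000
    ),
    "outside the protocol"
  )
})
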