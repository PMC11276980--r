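test_that("simulate_lfp is deterministic given a seed", {
  a <- simulate_lfp(lfp_sim_config(duration = 60, seed = 42))
  b <- simulate_lfp(lfp_sim_config(duration = 60, seed = 42))
  expect_identical(a$lfp$value, b$lfp$value)
  expect_identical(a$events$onset_s, b$events$onset_s)
  expect_identical(a$discharges, b$discharges)
  c <- simulate_lfp(lfp_sim_config(duration = 60, seed = 43))
  expect_false(identical(a$lfp$value, c$lfp$value))
})

test_that("ground truth is internally consistent", {
  sim <- simulate_lfp(lfp_sim_config(duration = 120, seed = 5,
                                     ictal_cluster_count = 2L))
  expect_equal(length(sim$classes), nrow(sim$events))
  expect_equal(nrow(sim$discharges), 2)
  expect_equal(sum(sim$classes == "ictal-member"), sum(sim$discharges$n_uees))
  # discharge spans contain exactly their member events
  for (i in seq_len(nrow(sim$discharges))) {
    m <- sim$discharges$member_times[[i]]
    expect_equal(length(m), sim$discharges$n_uees[i])
    expect_equal(min(m), sim$discharges$start_s[i])
    expect_equal(max(m), sim$discharges$end_s[i])
  }
  # the event train respects the detector lockout by construction
  expect_true(all(diff(sim$events$onset_s) >= 0.05 - 1e-9))
  expect_equal(nrow(sim$lfp), 120 * 10000)
})

test_that("polarity and amplitude are honored", {
  pos <- simulate_lfp(lfp_sim_config(duration = 30, seed = 1,
                                     ictal_cluster_count = 0L))
  neg <- simulate_lfp(lfp_sim_config(duration = 30, seed = 1,
                                     ictal_cluster_count = 0L,
                                     polarity = "negative"))
  expect_gt(max(pos$lfp$value), 6) # 8 x noise SD sharp lobes
  expect_lt(min(neg$lfp$value), -6)
})

test_that("interictal_rate = 0 gives clusters only", {
  sim <- simulate_lfp(lfp_sim_config(duration = 120, seed = 3,
                                     interictal_rate = 0))
  expect_true(all(sim$classes == "ictal-member"))
  expect_equal(nrow(sim$events), 3 * 30)
})

test_that("impossible configurations are rejected", {
  expect_error(
    simulate_lfp(lfp_sim_config(duration = 10, seed = 1)),
    "duration too short"
  )
  expect_error(lfp_sim_config(intra_cluster_interval = 0.04), "lockout")
  expect_error(lfp_sim_config(rate = 500), "rate")
  expect_error(lfp_sim_config(duration = 0), "duration")
})

test_that("planted interval distribution matches the configured renewal", {
  # pooled over seeds, the interictal gamma renewal (shape 4, rate 0.4) has
  # its log-density mode at the mean interval 2.5 s; the pause-and-resume
  # placement around clusters must not bias it
  pooled <- unlist(lapply(1:6, function(s) {
    sim <- simulate_lfp(lfp_sim_config(duration = 300, seed = s,
                                       ictal_cluster_count = 1L))
    iv <- diff(sim$events$onset_s[sim$classes == "interictal"])
    iv[iv < 10] # drop the single interval spanning the cluster pause
  }))
  d <- density(log10(pooled), bw = 0.08)
  mode <- 10^d$x[which.max(d$y)]
  expect_equal(mode, 2.5, tolerance = 0.15)
  # mean of a gamma renewal with rate 0.4 is 2.5 s
  expect_equal(mean(pooled), 2.5, tolerance = 0.1)
})

test_that("pink+white noise changes the spectrum, not the events", {
  a <- simulate_lfp(lfp_sim_config(duration = 60, seed = 8))
  b <- simulate_lfp(lfp_sim_config(duration = 60, seed = 8,
                                   noise_spectrum = "pink+white"))
  expect_identical(a$events$onset_s, b$events$onset_s)
  expect_false(identical(a$lfp$value, b$lfp$value))
})
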