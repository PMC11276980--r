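test_that("timeseries builds a tibble with correct time axis and attributes", {
  ts <- timeseries(c(0, 1, 2, 3), rate = 100, t0 = 0.5, units = "mV",
                   label = "chan1")
  expect_s3_class(ts, "eps_ts")
  expect_s3_class(ts, "tbl_df")
  expect_equal(names(ts), c("time_s", "value"))
  expect_equal(ts$time_s, 0.5 + (0:3) / 100)
  expect_equal(ts_rate(ts), 100)
  expect_equal(ts_t0(ts), 0.5)
  expect_equal(ts_units(ts), "mV")
  expect_equal(ts_label(ts), "chan1")
  expect_equal(ts_duration(ts), 4 / 100)
})

test_that("timeseries rejects bad input", {
  expect_error(timeseries(1, rate = 100), "at least 2")
  expect_error(timeseries(c(1, NA), rate = 100), "corrupt signal")
  expect_error(timeseries(c(1, Inf), rate = 100), "corrupt signal")
  expect_error(timeseries(c(1, 2), rate = 0), "sampling rate")
  expect_error(timeseries(c(1, 2), rate = -5), "sampling rate")
  expect_error(timeseries(c(1, 2), rate = NA_real_), "sampling rate")
})

test_that("step_protocol validates and stores its fields", {
  p <- step_protocol()
  expect_equal(p$step_onset, 0.25)
  expect_equal(p$step_duration, 1.5)
  expect_equal(p$amplitudes, seq(-100, 600, by = 20))
  expect_error(step_protocol(step_onset = -1), "step_onset")
  expect_error(step_protocol(step_duration = 0), "step_duration")
})

test_that("sweep_family builds long-format sweeps with metadata", {
  p <- step_protocol(amplitudes = c(-50, 0, 50))
  sw <- lapply(c(-50, 0, 50), function(a) {
    timeseries(rep(a, 10), rate = 1000, units = "mV")
  })
  fam <- sweep_family(sw, p)
  expect_s3_class(fam, "eps_sweeps")
  expect_equal(nrow(fam), 30)
  expect_equal(unique(fam$amplitude_pa), c(-50, 0, 50))
  expect_equal(family_rate(fam), 1000)
  expect_identical(family_protocol(fam), p)
  expect_error(sweep_family(sw[1:2], p), "one sweep per")
  sw[[2]] <- timeseries(rep(0, 5), rate = 1000, units = "mV")
  expect_error(sweep_family(sw, p), "share sampling rate and length")
})

test_that("event_train enforces ordering, bounds and lockout", {
  ev <- event_train(c(1, 2, 3.5), duration = 10)
  expect_s3_class(ev, "eps_events")
  expect_equal(events_duration(ev), 10)
  expect_equal(events_lockout(ev), 0.05)
  expect_equal(nrow(event_train(numeric(0), duration = 10)), 0)
  expect_error(event_train(c(2, 1), duration = 10), "strictly increasing")
  expect_error(event_train(c(1, 11), duration = 10), "\\[0, duration\\]")
  expect_error(event_train(c(1, 1.01), duration = 10), "lockout")
  # exactly at the lockout is allowed
  expect_silent(event_train(c(1, 1.05), duration = 10))
})

test_that("stim_markers validates ordering and records the pathway", {
  st <- stim_markers(c(0.1, 0.15), pathway = "schaffer")
  expect_equal(attr(st, "pathway"), "schaffer")
  expect_error(stim_markers(c(0.2, 0.1)), "strictly increasing")
})
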