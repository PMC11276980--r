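# closed-form squared Butterworth magnitude (zero-phase = forward-backward)
butter_mag2 <- function(f, fc, order) 1 / (1 + (f / fc)^(2 * order))

test_that("zero-phase Butterworth attenuation matches the analog formula", {
  # pure sinusoids through the full preprocess path; measure amplitude on the
  # middle half to avoid edge effects
  fs <- 2000
  cfg <- detection_config() # order 8, cutoff 100 Hz
  for (f in c(5, 25, 50, 75, 90, 95)) {
    t <- seq(0, 20, by = 1 / fs)
    sig <- timeseries(sin(2 * pi * f * t), rate = fs)
    out <- preprocess(sig, cfg)
    mid <- out$value[seq(round(0.25 * nrow(out)), round(0.75 * nrow(out)))]
    gain2 <- 2 * mean(mid^2) # amplitude^2 of a unit sinusoid
    expect_equal(gain2, butter_mag2(f, 100, 8)^2, tolerance = 0.02)
  }
  # above the cutoff the discrete design deviates from the analog formula
  # (bilinear warping), but attenuation must be strong
  for (f in c(110, 150)) {
    t <- seq(0, 20, by = 1 / fs)
    out <- preprocess(timeseries(sin(2 * pi * f * t), rate = fs), cfg)
    mid <- out$value[seq(round(0.25 * nrow(out)), round(0.75 * nrow(out)))]
    expect_lt(2 * mean(mid^2), 1.2 * butter_mag2(f, 100, 8)^2)
  }
})

test_that("preprocess decimates to the target rate and preserves duration", {
  sig <- timeseries(rnorm(50000), rate = 10000)
  out <- preprocess(sig, detection_config())
  expect_equal(ts_rate(out), 200)
  expect_equal(nrow(out), 1000)
  expect_equal(ts_duration(out), ts_duration(sig))
})

test_that("preprocess is zero-phase: a symmetric pulse keeps its center", {
  fs <- 10000
  n <- 20000
  x <- numeric(n)
  center <- 10000
  x[(center - 50):(center + 50)] <- sin(pi * seq(0, 1, length.out = 101))^2
  out <- preprocess(timeseries(x, rate = fs), detection_config())
  i_pk <- which.max(out$value)
  t_pk <- out$time_s[i_pk]
  expect_lt(abs(t_pk - (center - 1) / fs), 1.5 / 200)
})

test_that("preprocess rejects incompatible sampling rates", {
  expect_error(
    preprocess(timeseries(rnorm(100), rate = 300), detection_config()),
    "insufficient sampling rate"
  )
  expect_error(
    preprocess(timeseries(rnorm(1000), rate = 500), detection_config()),
    "integer multiple"
  )
})

test_that("already-at-target-rate input passes through unfiltered", {
  x <- rnorm(400)
  out <- preprocess(timeseries(x, rate = 200), detection_config())
  expect_equal(out$value, x)
})

test_that("optional high-pass removes drift but keeps fast transients", {
  fs <- 2000
  t <- seq(0, 30, by = 1 / fs)
  drift <- 5 * sin(2 * pi * 0.02 * t)
  x <- drift + rnorm(length(t), 0, 0.1)
  cfg <- detection_config(highpass = 1)
  out <- preprocess(timeseries(x, rate = fs), cfg)
  mid <- seq(round(0.25 * nrow(out)), round(0.75 * nrow(out)))
  expect_lt(sd(out$value[mid]), 0.5) # drift (sd ~3.5) largely removed
})

test_that("detection_config validates its arguments", {
  expect_error(detection_config(threshold_percentile = 100), "percentile")
  expect_error(detection_config(lockout = 0), "lockout")
  expect_error(detection_config(filter_order = 0), "filter_order")
})
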