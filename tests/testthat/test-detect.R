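test_that("compute_threshold is the requested percentile of the rectified signal", {
  x <- c(seq(-100, 100)) # median 0, symmetric
  sig <- timeseries(x, rate = 200)
  thr <- compute_threshold(sig, detection_config(threshold_percentile = 99))
  expect_equal(thr, unname(quantile(abs(x), 0.99, type = 7)))
  thr90 <- compute_threshold(sig, detection_config(threshold_percentile = 90,
                                                   polarity = "positive"))
  expect_equal(thr90, unname(quantile(x - median(x), 0.90, type = 7)))
})

test_that("compute_threshold on a constant signal is an error", {
  expect_error(
    compute_threshold(timeseries(rep(1, 100), rate = 200), detection_config()),
    "degenerate amplitude distribution"
  )
})

test_that("detection is invariant to positive rescaling", {
  set.seed(11)
  x <- rnorm(5000)
  x[c(500, 1500, 3000)] <- 30
  a <- timeseries(x, rate = 200)
  b <- timeseries(7.3 * x, rate = 200)
  cfg <- detection_config()
  ev_a <- detect_uees(a, compute_threshold(a, cfg), cfg)
  ev_b <- detect_uees(b, compute_threshold(b, cfg), cfg)
  expect_equal(ev_a$onset_s, ev_b$onset_s)
})

test_that("the lockout is non-retriggerable", {
  # impulses at 0 ms, 30 ms, 60 ms: the 30 ms one is suppressed by the
  # lockout from the first, and must NOT extend the lockout - the 60 ms
  # impulse is 60 ms after the last EMITTED event and is detected
  fs <- 1000
  x <- rnorm(2000, 0, 0.01)
  x[c(101, 131, 161)] <- 10
  sig <- timeseries(x, rate = fs)
  ev <- detect_uees(sig, 5, detection_config())
  expect_equal(ev$onset_s, c(100, 160) / fs, tolerance = 1e-9)
})

test_that("an exceedance exactly at the lockout boundary is emitted", {
  fs <- 1000
  x <- numeric(500)
  x[c(101, 151)] <- 10 # 50 ms apart exactly
  x <- x + rnorm(500, 0, 0.01)
  ev <- detect_uees(timeseries(x, rate = fs), 5, detection_config())
  expect_equal(nrow(ev), 2)
})

test_that("detect_uees matches the brute-force oracle on random signals", {
  set.seed(202)
  cfgs <- list(
    detection_config(),
    detection_config(polarity = "positive", lockout = 0.02),
    detection_config(polarity = "negative", threshold_percentile = 95)
  )
  for (rep in 1:20) {
    n <- sample(2000:20000, 1)
    x <- rnorm(n)
    k <- sample(5:40, 1)
    x[sample(n, k)] <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 8, 30)
    sig <- timeseries(x, rate = 1000)
    cfg <- cfgs[[1 + rep %% 3]]
    thr <- compute_threshold(sig, cfg)
    fast <- detect_uees(sig, thr, cfg)
    slow <- brute_force_detect(sig, thr, cfg)
    expect_equal(fast$onset_s, slow)
  }
})

test_that("detect_uees rejects nonsensical thresholds", {
  sig <- timeseries(rnorm(100), rate = 200)
  expect_error(detect_uees(sig, -1, detection_config()), "threshold")
  expect_error(detect_uees(sig, NA_real_, detection_config()), "threshold")
})
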