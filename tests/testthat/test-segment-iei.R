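test_that("segment_ictal finds exactly the dense runs", {
  # two dense runs (gaps 0.3 s) of 6 and 5 events, isolated events between
  times <- c(
    1, 3,
    10 + 0.3 * (0:5), # run of 6
    20,
    30 + 0.3 * (0:4), # run of 5
    40
  )
  ev <- event_train(times, duration = 50)
  seg <- segment_ictal(ev, ictal_config(max_gap = 1, min_events = 5))
  expect_equal(nrow(seg$discharges), 2)
  expect_equal(seg$discharges$start_s, c(10, 30))
  expect_equal(seg$discharges$end_s, c(11.5, 31.2))
  expect_equal(seg$discharges$n_uees, c(6L, 5L))
  expect_equal(sum(seg$classes == "ictal-member"), 11)
  expect_equal(length(seg$classes), length(times))
})

test_that("runs below min_events stay interictal", {
  times <- c(1, 10 + 0.3 * (0:3), 20) # run of only 4
  seg <- segment_ictal(event_train(times, 30),
                       ictal_config(max_gap = 1, min_events = 5))
  expect_equal(nrow(seg$discharges), 0)
  expect_true(all(seg$classes == "interictal"))
})

test_that("a gap exactly equal to max_gap stays within one discharge", {
  times <- c(5, 6, 7, 8, 9) # all gaps exactly 1
  seg <- segment_ictal(event_train(times, 20), ictal_config(max_gap = 1))
  expect_equal(nrow(seg$discharges), 1)
  seg2 <- segment_ictal(event_train(times, 20), ictal_config(max_gap = 0.999))
  expect_equal(nrow(seg2$discharges), 0)
})

test_that("segment_ictal handles empty trains", {
  seg <- segment_ictal(event_train(numeric(0), 10), ictal_config())
  expect_equal(nrow(seg$discharges), 0)
  expect_equal(seg$classes, character(0))
})

test_that("cumulative_curve is monotone and conserves the event count", {
  set.seed(4)
  times <- sort(runif(100, 0, 99))
  times <- times[c(TRUE, diff(times) >= 0.05)]
  ev <- event_train(times, duration = 100)
  cc <- cumulative_curve(ev, bin = 1)
  expect_true(all(diff(cc$count) >= 0))
  expect_equal(cc$count[nrow(cc)], nrow(ev))
  expect_equal(cc$count[1], sum(times <= 0))
})

test_that("activity_latency is the first onset", {
  expect_equal(activity_latency(event_train(c(12.5, 20), 100)), 12.5)
  expect_true(is.na(activity_latency(event_train(numeric(0), 100))))
})

test_that("iei_statistics recovers the modes of a bimodal interval mixture", {
  # deterministic intervals: 150 of 0.3 s and 150 of 2.5 s, shuffled
  set.seed(9)
  iv <- sample(c(rep(0.3, 150), rep(2.5, 150)))
  ev <- event_train(cumsum(c(1, iv)), duration = 600)
  st <- iei_statistics(ev)
  modes <- sort(st$modes[1:2])
  expect_equal(modes[1], 0.3, tolerance = 0.05)
  expect_equal(modes[2], 2.5, tolerance = 0.05)
  expect_equal(sum(st$histogram$count), length(iv))
  expect_equal(st$intervals, diff(ev$onset_s))
})

test_that("iei modes are ordered by peak height", {
  # 200 short intervals vs 50 long ones: the short mode must come first
  set.seed(10)
  iv <- sample(c(rep(0.3, 200), rep(2.5, 50)))
  st <- iei_statistics(event_train(cumsum(c(1, iv)), duration = 300))
  expect_equal(st$modes[1], 0.3, tolerance = 0.05)
})

test_that("iei_statistics needs at least 3 events", {
  expect_error(iei_statistics(event_train(c(1, 2), 10)), "too few events")
})
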