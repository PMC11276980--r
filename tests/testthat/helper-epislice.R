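# shared helpers for the test suite

# brute-force reference detector: sample scan with a non-retriggerable
# lockout, written as plainly as possible to serve as an oracle for
# detect_uees()
brute_force_detect <- function(sig, threshold, cfg = detection_config()) {
  x <- sig$value - stats::median(sig$value)
  x <- switch(cfg$polarity,
    absolute = abs(x),
    positive = x,
    negative = -x
  )
  fs <- ts_rate(sig)
  onsets <- numeric(0)
  last_idx <- -Inf
  for (i in seq_along(x)) {
    if (x[i] > threshold && (i == 1L || x[i - 1L] <= threshold)) {
      if ((i - last_idx) / fs >= cfg$lockout - 1e-12) {
        onsets <- c(onsets, (i - 1) / fs + ts_t0(sig))
        last_idx <- i
      }
    }
  }
  onsets
}

# match detections to planted onsets within +/- tol seconds
match_events <- function(detected, planted, tol = 0.025) {
  is_tp <- vapply(detected, function(t) any(abs(planted - t) <= tol), logical(1))
  recalled <- vapply(planted, function(t) any(abs(detected - t) <= tol), logical(1))
  list(
    n_det = length(detected), n_true = length(planted),
    n_fp = sum(!is_tp), recall = mean(recalled)
  )
}

# run the full default detection pipeline on a simulated recording
run_pipeline <- function(sim, cfg = detection_config()) {
  pp <- preprocess(sim$lfp, cfg)
  thr <- compute_threshold(pp, cfg)
  detect_uees(pp, thr, cfg)
}

relerr <- function(est, truth) abs(est - truth) / abs(truth)
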