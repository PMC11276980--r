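# median-subtract and apply the configured polarity; the detector and the
# threshold estimator must share this transformation exactly
rectify <- function(x, cfg) {
  x <- x - median(x)
  switch(cfg$polarity,
    absolute = abs(x),
    positive = x,
    negative = -x
  )
}

#' Amplitude threshold from the rectified amplitude distribution
#'
#' The event threshold is read off the amplitude histogram of the whole
#' recording: after median subtraction and rectification (per the configured
#' polarity), the threshold is the configured percentile (default 99th) of
#' all sample amplitudes. Epileptiform transients are much larger than the
#' noise floor but occupy a small fraction of the recording, so this
#' percentile falls between the noise body and the event amplitudes. Because
#' the threshold is a percentile, detection is invariant to positive
#' rescaling of the signal - no amplitude calibration is needed.
#'
#' Percentile convention: linear interpolation between order statistics
#' (type 7 in [stats::quantile()]).
#'
#' @param sig preprocessed signal ([preprocess()]).
#' @param cfg a [detection_config()].
#' @return scalar threshold in the units of `sig`.
#' @export
compute_threshold <- function(sig, cfg = detection_config()) {
  validate_timeseries(sig)
  r <- rectify(sig$value, cfg)
  if (max(r) - min(r) <= 0) abort("degenerate amplitude distribution")
  unname(quantile(r, cfg$threshold_percentile / 100, type = 7))
}

#' Detect unitary epileptiform events
#'
#' Scans the rectified signal for threshold crossings. The onset of a uEE is
#' the first sample at which the amplitude exceeds the threshold; any further
#' exceedance within the refractory lockout (default 50 ms) after an emitted
#' event is ignored, so a multiphasic discharge yields a single event. The
#' lockout is non-retriggerable: it runs from the emitted onset only, and
#' suppressed crossings do not extend it.
#'
#' @param sig preprocessed signal.
#' @param threshold amplitude threshold, same units as `sig`; typically from
#'   [compute_threshold()].
#' @param cfg a [detection_config()].
#' @return an [event_train()] (possibly empty).
#' @export
detect_uees <- function(sig, threshold, cfg = detection_config()) {
  validate_timeseries(sig)
  if (!is.finite(threshold) || threshold <= 0) abort("threshold must be > 0")
  r <- rectify(sig$value, cfg)
  above <- r > threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  fs <- ts_rate(sig)
  lock_n <- cfg$lockout * fs
  onsets <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (i - last >= lock_n - 1e-9) {
      onsets <- c(onsets, i)
      last <- i
    }
  }
  event_train((onsets - 1) / fs + ts_t0(sig),
    duration = ts_duration(sig), lockout = cfg$lockout
  )
}

#' Ictal segmentation configuration
#'
#' An ictal discharge is operationalized as a dense run of uEEs: successive
#' gaps no longer than `max_gap` and at least `min_events` members. The
#' default gap of 1 s sits between the two modes of the inter-event-interval
#' distribution (about 0.3 s within ictal discharges versus a few seconds
#' between interictal events), and 5 members excludes short interictal
#' bursts.
#'
#' @param max_gap maximum gap between successive member events, s.
#' @param min_events minimum number of member events (>= 2).
#' @return an `ictal_config` list.
#' @export
ictal_config <- function(max_gap = 1.0, min_events = 5L) {
  if (min_events < 2) abort("min_events must be >= 2")
  if (max_gap <= 0) abort("max_gap must be > 0")
  structure(list(max_gap = max_gap, min_events = as.integer(min_events)),
    class = "ictal_config"
  )
}

#' Segment ictal discharges from an event train
#'
#' Single-linkage clustering in time: maximal runs of events whose successive
#' gaps are all `<= max_gap` become ictal discharges when they contain at
#' least `min_events` events; all remaining events are interictal. Every
#' event is classified exactly once.
#'
#' @param events an [event_train()].
#' @param cfg an [ictal_config()].
#' @return a list: `discharges` (tibble `start_s`, `end_s`, `n_uees`,
#'   `member_times` list column) and `classes` (character vector parallel to
#'   `events`, `"interictal"` or `"ictal-member"`).
#' @export
segment_ictal <- function(events, cfg = ictal_config()) {
  stopifnot(inherits(events, "eps_events"))
  t <- events$onset_s
  n <- length(t)
  empty <- tibble(
    start_s = numeric(), end_s = numeric(), n_uees = integer(),
    member_times = list()
  )
  if (n == 0L) return(list(discharges = empty, classes = character(0)))
  run_id <- cumsum(c(1, as.integer(diff(t) > cfg$max_gap)))
  classes <- rep("interictal", n)
  runs <- split(seq_len(n), run_id)
  keep <- runs[lengths(runs) >= cfg$min_events]
  discharges <- purrr::map_dfr(keep, function(idx) {
    tibble(
      start_s = t[idx[1]], end_s = t[idx[length(idx)]],
      n_uees = length(idx), member_times = list(t[idx])
    )
  })
  if (nrow(discharges) == 0L) discharges <- empty
  for (idx in keep) classes[idx] <- "ictal-member"
  validate_discharges(discharges)
  list(discharges = discharges, classes = classes)
}

#' Cumulative event-count curve
#'
#' The cumulative number of detected uEEs as a function of time. Ictal
#' discharges appear as steeply rising steps; interictal activity produces a
#' gentle slope, so the curve gives an at-a-glance picture of how
#' epileptiform activity develops over a recording.
#'
#' @param events an [event_train()].
#' @param bin time resolution of the grid, s.
#' @return tibble with columns `time_s`, `count` (non-decreasing; final value
#'   equals the total event count).
#' @export
cumulative_curve <- function(events, bin = 1.0) {
  stopifnot(inherits(events, "eps_events"))
  if (bin <= 0) abort("bin must be > 0")
  dur <- events_duration(events)
  grid <- seq(0, dur + bin, by = bin)
  grid <- grid[grid <= dur + bin]
  counts <- vapply(grid, function(g) sum(events$onset_s <= g), numeric(1))
  tibble(time_s = grid, count = counts)
}

#' Latency to first epileptiform activity
#'
#' Time from the start of the recording (the moment of the solution change
#' when the recording is aligned to it) to the first detected event.
#'
#' @param events an [event_train()].
#' @return first onset in seconds, or `NA_real_` for an empty train.
#' @export
activity_latency <- function(events) {
  stopifnot(inherits(events, "eps_events"))
  if (nrow(events) == 0L) return(NA_real_)
  events$onset_s[1]
}
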