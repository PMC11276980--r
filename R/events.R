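#' Construct an event train
#'
#' Ordered onset times of unitary epileptiform events (uEEs) within a
#' recording. Produced by [detect_uees()] and by the synthetic generator;
#' consumed by every event statistic.
#'
#' @param times event onset times in seconds, strictly increasing.
#' @param duration recording duration in seconds.
#' @param lockout the refractory lockout (s) in force when the train was
#'   produced; consecutive onsets must be at least this far apart.
#' @return tibble of class `eps_events` with column `onset_s`.
#' @export
event_train <- function(times, duration, lockout = 0.05) {
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times))) abort("event times must be finite")
    if (any(diff(times) <= 0)) abort("event times must be strictly increasing")
    if (min(times) < 0 || max(times) > duration) {
      abort("event times must lie in [0, duration]")
    }
    if (length(times) > 1L && any(diff(times) < lockout - 1e-9)) {
      abort("consecutive events closer than the lockout")
    }
  }
  out <- tibble(onset_s = times)
  structure(out,
    class = c("eps_events", class(out)),
    duration = as.numeric(duration), lockout = as.numeric(lockout)
  )
}

#' @rdname event_train
#' @param events an `eps_events` object.
#' @export
events_duration <- function(events) attr(events, "duration")

#' @rdname event_train
#' @export
events_lockout <- function(events) attr(events, "lockout")

# validate a tibble of ictal discharges (start_s, end_s, n_uees [, member
# times in a list column])
validate_discharges <- function(discharges) {
  if (nrow(discharges) == 0L) return(invisible(discharges))
  if (any(discharges$end_s <= discharges$start_s)) {
    abort("discharge with end <= start")
  }
  d <- dplyr::arrange(discharges, .data$start_s)
  if (nrow(d) > 1L && any(d$start_s[-1] < d$end_s[-nrow(d)])) {
    abort("overlapping discharges")
  }
  invisible(discharges)
}

#' Write and read event annotations
#'
#' Plain-text annotation format shared by the detector and the synthetic
#' generator: a CSV with columns `kind,start_s,end_s,n_uees,class`. Each
#' event contributes one `uee` row (`start_s` = `end_s` = onset,
#' `class` either `interictal` or `ictal-member`); each ictal discharge
#' contributes one `ictal` row with its span and event count. The recording
#' duration is carried in a `#` header line so the round trip is lossless.
#'
#' @param events an [event_train()].
#' @param discharges tibble of ictal discharges (`start_s`, `end_s`,
#'   `n_uees`), e.g. from [segment_ictal()]; may have zero rows.
#' @param path output file.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   a list with elements `events` and `discharges`.
#' @export
write_events <- function(events, discharges, path) {
  stopifnot(inherits(events, "eps_events"))
  validate_discharges(discharges)
  cls <- rep("interictal", nrow(events))
  if (nrow(discharges)) {
    for (i in seq_len(nrow(discharges))) {
      in_d <- events$onset_s >= discharges$start_s[i] - 1e-9 &
        events$onset_s <= discharges$end_s[i] + 1e-9
      cls[in_d] <- "ictal-member"
    }
  }
  rows <- dplyr::bind_rows(
    tibble(
      kind = "uee", start_s = events$onset_s, end_s = events$onset_s,
      n_uees = NA_integer_, class = cls
    ),
    tibble(
      kind = "ictal", start_s = discharges$start_s, end_s = discharges$end_s,
      n_uees = as.integer(discharges$n_uees), class = NA_character_
    )
  )
  con <- file(path, "w")
  on.exit(close(con))
  meta <- jsonlite::toJSON(
    list(duration_s = events_duration(events), lockout_s = events_lockout(events)),
    auto_unbox = TRUE, digits = NA
  )
  writeLines(paste0("# ", meta), con)
  writeLines("kind,start_s,end_s,n_uees,class", con)
  if (nrow(rows)) {
    writeLines(paste(rows$kind, fmt_num(rows$start_s), fmt_num(rows$end_s),
      ifelse(is.na(rows$n_uees), "", rows$n_uees),
      ifelse(is.na(rows$class), "", rows$class),
      sep = ","
    ), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# ")) {
    abort("missing annotation metadata header")
  }
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  body <- lines[-(1:2)]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    parts <- lapply(parts, function(p) c(p, rep("", 5 - length(p))))
    m <- do.call(rbind, parts)
    tab <- tibble(
      kind = m[, 1],
      start_s = as.numeric(m[, 2]), end_s = as.numeric(m[, 3]),
      n_uees = suppressWarnings(as.integer(m[, 4])),
      class = ifelse(m[, 5] == "", NA_character_, m[, 5])
    )
  } else {
    tab <- tibble(
      kind = character(), start_s = numeric(), end_s = numeric(),
      n_uees = integer(), class = character()
    )
  }
  uee <- dplyr::filter(tab, .data$kind == "uee")
  ict <- dplyr::filter(tab, .data$kind == "ictal")
  list(
    events = event_train(uee$start_s,
      duration = meta$duration_s, lockout = meta$lockout_s
    ),
    classes = uee$class,
    discharges = tibble(
      start_s = ict$start_s, end_s = ict$end_s, n_uees = ict$n_uees
    )
  )
}

fmt_num <- function(x) formatC(x, digits = 12, format = "g")
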