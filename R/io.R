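#' Read and write time-series files
#'
#' Two neutral on-disk representations are supported. `"csv"` is a
#' two-column text table (`time_s,value`) whose first line is a `#` comment
#' carrying JSON metadata (`rate_hz`, `units`, `label`, `t0_s`); values are
#' printed with 12 significant digits, so a round trip reproduces the signal
#' to well below 1e-9 of its range. `"container"` is a single-file binary
#' container (serialized R object with `signal`, `rate`, `units`, `label`
#' fields) that round-trips bit-exactly. Vendor acquisition formats are not
#' parsed; export from the acquisition software into either of these.
#'
#' Metadata is mandatory: a CSV without a rate in its header is rejected
#' rather than guessed, and non-finite samples abort the read.
#'
#' @param ts an [timeseries()] object.
#' @param path file path.
#' @param format `"csv"` or `"container"`.
#' @return `read_timeseries()` returns a validated `eps_ts`;
#'   `write_timeseries()` returns `path` invisibly.
#' @export
write_timeseries <- function(ts, path, format = c("csv", "container")) {
  format <- match.arg(format)
  validate_timeseries(ts)
  if (format == "container") {
    obj <- list(
      signal = ts$value, rate = ts_rate(ts), units = ts_units(ts),
      label = ts_label(ts), t0 = ts_t0(ts)
    )
    saveRDS(obj, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  meta <- jsonlite::toJSON(
    list(
      rate_hz = ts_rate(ts), units = ts_units(ts), label = ts_label(ts),
      t0_s = ts_t0(ts)
    ),
    auto_unbox = TRUE, digits = NA
  )
  writeLines(paste0("# ", meta), con)
  writeLines("time_s,value", con)
  writeLines(paste(fmt_num(ts$time_s), fmt_num(ts$value), sep = ","), con)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, format = c("csv", "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "container") {
    obj <- readRDS(path)
    if (is.null(obj$rate)) abort("unspecified sampling rate")
    return(timeseries(obj$signal,
      rate = obj$rate, t0 = obj$t0 %||% 0,
      units = obj$units %||% "a.u.", label = obj$label %||% "signal"
    ))
  }
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) abort("unspecified sampling rate")
  meta <- tryCatch(jsonlite::fromJSON(sub("^#\\s*", "", header)),
    error = function(e) abort("unspecified sampling rate")
  )
  if (is.null(meta$rate_hz)) abort("unspecified sampling rate")
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(is.finite(tab$value))) abort("corrupt signal: non-finite samples")
  timeseries(tab$value,
    rate = meta$rate_hz, t0 = meta$t0_s %||% 0,
    units = meta$units %||% "a.u.", label = meta$label %||% "signal"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
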