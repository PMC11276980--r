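#' Assemble a structured analysis report
#'
#' Collects the results of the detection, patch-clamp and synaptic analyses
#' for one recording into a single JSON-ready document with provenance
#' (package version, configuration, seed). Sections are optional: a
#' detection-only run yields a report with only the LFP section. When the
#' inputs come from the synthetic generator, pass the generator's ground
#' truth through `ground_truth` so downstream scoring has the planted
#' values alongside the measured ones. Output is deterministic given the
#' same inputs.
#'
#' @param lfp optional list for the LFP section: `events`
#'   ([event_train()]), `discharges` + `classes` ([segment_ictal()] output),
#'   `iei` ([iei_statistics()] output).
#' @param passive optional [estimate_passive()] result.
#' @param firing optional [firing_pattern()] result.
#' @param ap optional [ap_features()] row (or several, row-bound).
#' @param synaptic optional [measure_train()] result.
#' @param ground_truth optional list of planted generator parameters.
#' @param config optional configuration list to embed.
#' @param seed optional seed to embed.
#' @param path optional file; when given, the JSON document is written
#'   there.
#' @return the report as a named list (invisibly, when `path` is given).
#' @export
build_report <- function(lfp = NULL, passive = NULL, firing = NULL, ap = NULL,
                         synaptic = NULL, ground_truth = NULL, config = NULL,
                         seed = NULL, path = NULL) {
  if (is.null(lfp) && is.null(passive) && is.null(firing) && is.null(ap) &&
    is.null(synaptic)) {
    abort("at least one analysis result is required")
  }
  report <- list(
    provenance = list(
      package = "epislice",
      version = as.character(packageVersion("epislice")),
      seed = seed, config = config
    )
  )
  if (!is.null(lfp)) {
    ev <- lfp$events
    seg <- lfp
    report$lfp <- list(
      n_uees = nrow(ev),
      latency_s = activity_latency(ev),
      n_ictal = if (!is.null(seg$discharges)) nrow(seg$discharges) else NULL,
      discharges = if (!is.null(seg$discharges)) {
        lapply(seq_len(nrow(seg$discharges)), function(i) {
          list(
            start_s = seg$discharges$start_s[i],
            end_s = seg$discharges$end_s[i],
            n_uees = seg$discharges$n_uees[i]
          )
        })
      } else {
        NULL
      },
      iei_modes_s = if (!is.null(seg$iei)) seg$iei$modes else NULL
    )
  }
  if (!is.null(passive)) {
    report$passive <- list(
      rmp_mv = passive$rmp, r_in_mohm = passive$r_in, tau_m_ms = passive$tau_m
    )
  }
  if (!is.null(firing)) {
    report$firing <- list(
      rheobase_pa = firing$rheobase,
      time_of_first_spike_ms = firing$time_of_first_spike,
      max_rate_hz = firing$max_rate,
      current_at_max_pa = firing$current_at_max,
      block_current_pa = firing$block_current,
      max_fi_slope_hz_per_pa = firing$max_fi_slope,
      early_adaptation = firing$early_adaptation,
      late_adaptation = firing$late_adaptation,
      fi_curve = as.list(firing$fi_curve)
    )
  }
  if (!is.null(ap)) {
    report$ap_features <- lapply(
      as.list(tibble::as_tibble(ap)), function(col) unname(col)
    )
  }
  if (!is.null(synaptic)) {
    report$synaptic <- list(
      pathway = synaptic$pathway,
      amplitudes_pa = synaptic$amplitudes,
      normalized = synaptic$normalized,
      ppr = synaptic$ppr
    )
  }
  if (!is.null(ground_truth)) report$ground_truth <- ground_truth
  if (!is.null(path)) {
    jsonlite::write_json(report, path,
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
    return(invisible(report))
  }
  report
}
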