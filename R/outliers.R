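#' Robust outlier screen by modified z-score
#'
#' The Iglewicz-Hoaglin robust test for multiple outliers: the modified
#' z-score of each value is
#' `M_i = 0.6745 * (x_i - median(x)) / MAD(x)`, with
#' `MAD = median(|x_i - median(x)|)` (unscaled), and values with
#' `|M_i| > threshold` are flagged (two-tailed; the conventional cutoff is
#' 3.5). The statistic is invariant under affine transforms of the data, and
#' a zero MAD (more than half the values tied) is an error rather than a
#' silent fallback.
#'
#' The test is single-pass; when screening iteratively, remove flagged
#' values and recompute.
#'
#' @param values numeric vector, length >= 3.
#' @param threshold two-tailed cutoff on `|M|`.
#' @return object of class `outlier_screen`: tibble with columns `value`,
#'   `modified_z`, `flag`; the threshold rides along as an attribute.
#' @export
iglewicz_hoaglin <- function(values, threshold = 3.5) {
  if (length(values) < 3L) abort("need at least 3 values")
  if (!all(is.finite(values))) abort("values must be finite")
  med <- median(values)
  mad0 <- median(abs(values - med))
  if (mad0 == 0) abort("degenerate spread")
  m <- 0.6745 * (values - med) / mad0
  out <- tibble(value = values, modified_z = m, flag = abs(m) > threshold)
  structure(out, class = c("outlier_screen", class(out)), threshold = threshold)
}
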