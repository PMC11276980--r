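#' Two-group comparison with normality check
#'
#' The standard screen applied to per-cell or per-slice measures: a
#' Kolmogorov-Smirnov normality check on each group (one-sample test
#' against a normal with moments estimated from the data - note the
#' Lilliefors caveat: estimated parameters make the nominal p-values
#' conservative guides only), followed by an unpaired two-sample Student's
#' t-test (pooled variance). Group summaries are reported as mean and
#' standard error of the mean. Both tests delegate to [stats::ks.test()]
#' and [stats::t.test()].
#'
#' @param a,b numeric vectors, length >= 2 each.
#' @param label_a,label_b group labels for the report.
#' @return object of class `group_comparison`: a list with the per-group
#'   summary tibble (`n`, `mean`, `sem`, `ks_p`), `t_statistic`, `df`,
#'   `p_value`.
#' @export
compare_groups <- function(a, b, label_a = "group_a", label_b = "group_b") {
  if (length(a) < 2L || length(b) < 2L) abort("need at least 2 values per group")
  ks_p <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  tt <- t.test(a, b, var.equal = TRUE)
  structure(
    list(
      groups = tibble(
        group = c(label_a, label_b),
        n = c(length(a), length(b)),
        mean = c(mean(a), mean(b)),
        sem = c(sd(a) / sqrt(length(a)), sd(b) / sqrt(length(b))),
        ks_p = c(ks_p(a), ks_p(b))
      ),
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  g <- x$groups
  for (i in 1:2) {
    cat(sprintf(
      "  %s: %.3f +/- %.3f (n = %d, KS p = %s)\n",
      g$group[i], g$mean[i], g$sem[i], g$n[i], format(g$ks_p[i], digits = 3)
    ))
  }
  cat(sprintf(
    "  t = %.4f, df = %g, p = %s\n", x$t_statistic, x$df,
    format(x$p_value, digits = 4)
  ))
  invisible(x)
}
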