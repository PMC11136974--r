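#' Printed meat-quality summary statistics
#'
#' The published phenotype table of the 16-pig feeding trial (normal
#' calcium, NC, vs calcium-supplemented, HC; n = 8 per group): growth
#' performance and longissimus dorsi meat-quality traits as printed means,
#' SDs and group sizes, shipped with the package.
#'
#' @return `data.frame` with one row per trait: `item`, `mean_nc`,
#'   `sd_nc`, `n_nc`, `mean_hc`, `sd_hc`, `n_hc`,
#'   `printed_significance`.
#' @export
meat_quality_summary <- function() {
  read_table_tsv(system.file("extdata", "pig_meat_quality_summary.tsv",
                             package = "riboquad", mustWork = TRUE))
}

#' Recompute phenotype t-tests from printed summary statistics
#'
#' Applies [ttest_from_summary()] (two-tailed pooled Student t) to each
#' trait of [meat_quality_summary()] or of a table with the same schema.
#'
#' @param summary_table defaults to [meat_quality_summary()].
#' @param welch use Welch's form instead of the pooled Student t.
#' @return input table with `t`, `df`, `pvalue` columns appended.
#' @export
phenotype_ttests <- function(summary_table = meat_quality_summary(),
                             welch = FALSE) {
  res <- t(mapply(function(m1, s1, n1, m2, s2, n2) {
    tt <- ttest_from_summary(m1, s1, n1, m2, s2, n2, welch = welch)
    c(t = tt$t, df = tt$df, pvalue = tt$pvalue)
  }, summary_table$mean_nc, summary_table$sd_nc, summary_table$n_nc,
     summary_table$mean_hc, summary_table$sd_hc, summary_table$n_hc))
  cbind(summary_table, as.data.frame(res))
}
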