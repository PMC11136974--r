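#' Translation efficiency table
#'
#' TE for gene g in sample s is `RPKM_RFP / RPKM_RNA`. A gene is eligible
#' iff its group-mean RPKM reaches `min_rpkm` in *both* assays in *both*
#' groups (guards against division blow-ups at the detection limit); only
#' eligible genes enter TE statistics. Within an eligible gene, a sample
#' with zero RNA RPKM has undefined TE (NA) but the gene keeps its other
#' samples.
#'
#' @param rna_rpkm,rfp_rpkm matched gene x sample RPKM matrices.
#' @param groups two-level factor per sample.
#' @param min_rpkm eligibility threshold (default 0.1).
#' @return list of class `te_table`: `te`, `log2_te` (eligible genes x
#'   samples), `group_mean_log2_te` (eligible genes x groups), `eligible`
#'   (named logical over all genes), `groups`.
#' @export
compute_te <- function(rna_rpkm, rfp_rpkm, groups, min_rpkm = 0.1) {
  stopifnot(identical(dim(rna_rpkm), dim(rfp_rpkm)),
            identical(rownames(rna_rpkm), rownames(rfp_rpkm)))
  groups <- droplevels(as.factor(groups))
  gm <- function(m, g) rowMeans(m[, groups == g, drop = FALSE])
  eligible <- rep(TRUE, nrow(rna_rpkm))
  for (g in levels(groups))
    eligible <- eligible & gm(rna_rpkm, g) >= min_rpkm &
                gm(rfp_rpkm, g) >= min_rpkm
  names(eligible) <- rownames(rna_rpkm)
  te <- rfp_rpkm[eligible, , drop = FALSE] / rna_rpkm[eligible, , drop = FALSE]
  te[!is.finite(te)] <- NA
  log2_te <- log2(te)
  log2_te[!is.finite(log2_te)] <- NA
  gmean <- vapply(levels(groups), function(g)
    rowMeans(log2_te[, groups == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(log2_te)))
  structure(list(te = te, log2_te = log2_te, group_mean_log2_te = gmean,
                 eligible = eligible, groups = groups),
            class = "te_table")
}

#' Differential translation efficiency
#'
#' Per gene, a pooled two-sample t-test on replicate log2 TE values
#' (group 2 minus group 1), with the same fold-change >= 2 and P < 0.05
#' calling rule as the count-based analyses. Genes with fewer than 2
#' defined TE values in either group are excluded and tallied in
#' `attr(, "n_skipped")`.
#'
#' @param te a [compute_te()] result.
#' @param lfc_min,alpha calling thresholds; see [call_degs()].
#' @return `data.frame` of class `differential_result`: `gene_id`,
#'   `log2fc` (delta log2 TE), `pvalue`, `qvalue`, per-group mean log2 TE,
#'   `call`.
#' @export
diff_te <- function(te, lfc_min = 1, alpha = 0.05) {
  stopifnot(inherits(te, "te_table"))
  groups <- te$groups
  lv <- levels(groups)
  x <- te$log2_te[, groups == lv[1], drop = FALSE]
  y <- te$log2_te[, groups == lv[2], drop = FALSE]
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  ok <- n1 >= 2 & n2 >= 2
  n_skipped <- sum(!ok)
  res <- t(vapply(which(ok), function(i) {
    xi <- x[i, !is.na(x[i, ])]; yi <- y[i, !is.na(y[i, ])]
    tt <- ttest_from_summary(mean(xi), stats::sd(xi), length(xi),
                             mean(yi), stats::sd(yi), length(yi))
    c(mean(yi) - mean(xi), tt$pvalue, mean(xi), mean(yi))
  }, numeric(4)))
  out <- data.frame(gene_id = rownames(te$log2_te)[ok],
                    log2fc = res[, 1], pvalue = res[, 2],
                    qvalue = stats::p.adjust(res[, 2], "BH"),
                    mean_log2_te_1 = res[, 3], mean_log2_te_2 = res[, 4],
                    call = call_degs(res[, 1], res[, 2], lfc_min, alpha),
                    stringsAsFactors = FALSE)
  names(out)[5:6] <- paste0("mean_log2_te_", lv)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("differential_result", "data.frame")
  out
}

# Nine-quadrant letters on the 3x3 grid, x = transcription state,
# y = translation state:
#   A(x down, y up)   B(x unch, y up)   C(x up, y up)
#   D(x down, y unch) E(x unch, y unch) F(x up, y unch)
#   G(x down, y down) H(x unch, y down) I(x up, y down)
quadrant_grid <- matrix(c("A", "B", "C",
                          "D", "E", "F",
                          "G", "H", "I"),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(trans = c("up", "unchanged", "down"),
                                        txn = c("down", "unchanged", "up")))

#' Nine-quadrant transcriptome/translatome classification
#'
#' Joins the transcriptional (RNA) and translational (RFP) differential
#' results on their shared gene universe and assigns each gene one of the
#' nine quadrant letters A-I (see the grid in the package vignette):
#' B and H hold translation-only genes, D and F transcription-only genes,
#' C and G concordant changes, E no change. Genes missing from either
#' analysis are excluded and tallied in `attr(, "n_missing")`.
#'
#' @param txn,trans `differential_result` tables for RNA and RFP.
#' @return `data.frame` of class `quadrant_table`: `gene_id`, `txn_state`,
#'   `trans_state`, `quadrant`.
#' @export
quadrant_classify <- function(txn, trans) {
  shared <- intersect(txn$gene_id, trans$gene_id)
  n_missing <- length(union(txn$gene_id, trans$gene_id)) - length(shared)
  state <- function(df) {
    s <- df$call[match(shared, df$gene_id)]
    ifelse(s == "ns", "unchanged", s)
  }
  xs <- state(txn); ys <- state(trans)
  out <- data.frame(gene_id = shared, txn_state = xs, trans_state = ys,
                    quadrant = quadrant_grid[cbind(match(ys, rownames(quadrant_grid)),
                                                   match(xs, colnames(quadrant_grid)))],
                    stringsAsFactors = FALSE)
  attr(out, "n_missing") <- n_missing
  class(out) <- c("quadrant_table", "data.frame")
  out
}

#' Translation-only genes (quadrants B and H)
#'
#' Genes translationally altered but transcriptionally unchanged, in
#' deterministic (gene id) order.
#'
#' @param quadrants a [quadrant_classify()] result.
#' @return character vector of gene ids.
#' @export
translation_only_set <- function(quadrants) {
  sort(quadrants$gene_id[quadrants$quadrant %in% c("B", "H")])
}

#' Transcription-only genes (quadrants D and F)
#' @inheritParams translation_only_set
#' @return character vector of gene ids.
#' @export
transcription_only_set <- function(quadrants) {
  sort(quadrants$gene_id[quadrants$quadrant %in% c("D", "F")])
}

#' Ordinary least-squares fit with R-squared
#'
#' @param x,y per-gene values; pairs with non-finite entries are dropped;
#'   at least 3 finite pairs and nonzero variance in `x` are required.
#' @return list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_("need >= 3 finite pairs")
  if (stats::var(x) == 0) stop_("zero variance in x")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = length(x)),
            class = "regression_fit")
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. When `n1 * n2 <= exact_max`
#' and there are no ties, the two-sided p-value is exact (doubled smaller
#' tail of the null U distribution, capped at 1); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param valuesA,valuesB non-empty numeric vectors.
#' @param exact_max product-of-sizes bound for the exact branch
#'   (default 400).
#' @return list of class `rank_test_result`: `U` (for group A), `pvalue`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(valuesA, valuesB, exact_max = 400) {
  n1 <- length(valuesA); n2 <- length(valuesB)
  if (n1 == 0 || n2 == 0) stop_("both groups must be non-empty")
  all_v <- c(valuesA, valuesB)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(all_v))
  if (!ties && n1 * n2 <= exact_max) {
    lower <- stats::pwilcox(U, n1, n2)
    upper <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_sizes <- table(all_v)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(U = U, pvalue = p, method = method),
            class = "rank_test_result")
}

#' Empirical cumulative distribution table
#'
#' Right-continuous ECDF as a step-function table over the sorted unique
#' values; the final cumulative fraction is 1.
#'
#' @param values non-empty numeric vector.
#' @return `data.frame` with `value` and `fraction`.
#' @export
ecdf_table <- function(values) {
  if (!length(values)) stop_("values must be non-empty")
  v <- sort(unique(values))
  data.frame(value = v,
             fraction = cumsum(as.integer(table(factor(sort(values),
                                                       levels = v)))) / length(values))
}
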