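#' Equalize library sizes by geometric-mean scaling
#'
#' The conditional exact test assumes equal library sizes. Counts are
#' scaled to the geometric mean of the observed library sizes and rounded
#' half-to-even; adjusted library sizes are recomputed from the adjusted
#' counts.
#'
#' @param counts gene x sample count matrix.
#' @param lib_sizes per-sample totals (default: column sums).
#' @return list: `counts` (adjusted integer matrix), `lib_sizes`
#'   (recomputed), `common_size`.
#' @export
equalize_libraries <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop_("all library sizes must be positive")
  common <- exp(mean(log(lib_sizes)))
  adj <- round(sweep(counts, 2, common / lib_sizes, "*"))
  storage.mode(adj) <- "integer"
  list(counts = adj, lib_sizes = colSums(adj), common_size = common)
}

# Conditional NB log-likelihood of within-group counts given their sum
# (equal within-group means). For n iid NB(r, p) replicates with counts y
# and total z, P(y | z) = prod_i C(y_i+r-1, y_i) / C(z+nr-1, z); p cancels.
cond_loglik <- function(phi, counts, groups) {
  r <- 1 / phi
  total <- 0
  for (g in levels(groups)) {
    y <- counts[, groups == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    total <- total +
      sum(lgamma(y + r) - lgamma(y + 1)) - length(y) * lgamma(r) -
      sum(lgamma(z + n * r) - lgamma(z + 1) - lgamma(n * r))
  }
  total
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' Maximizes, over genes and groups, the conditional log-likelihood of the
#' within-group counts given their group totals under a common-dispersion
#' NB model (variance = mu + phi mu^2). The maximum is located by
#' golden-section search on `[1e-6, 10]` to tolerance `1e-4`. Counts
#' should be library-equalized first.
#'
#' @param counts gene x sample integer matrix (library-equalized).
#' @param groups factor with >= 2 samples per group.
#' @return list of class `dispersion_estimate`: `phi`, `method`,
#'   `n_genes_used`.
#' @export
estimate_common_dispersion <- function(counts, groups) {
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2)) stop_("need >= 2 samples per group")
  use <- rowSums(counts) > 0
  if (sum(use) < 10)
    warn_("fewer than 10 genes usable for dispersion estimation")
  y <- counts[use, , drop = FALSE]
  f <- function(phi) cond_loglik(phi, y, groups)
  phi <- golden_section_max(f, 1e-6, 10, tol = 1e-4)
  structure(list(phi = phi, method = "conditional_ml_common",
                 n_genes_used = sum(use)),
            class = "dispersion_estimate")
}

# Golden-section maximization on [a, b] to absolute x tolerance `tol`.
golden_section_max <- function(f, a, b, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Conditional NB exact test for a two-group count difference
#'
#' Conditions on the total `T = sum(countsA) + sum(countsB)` (counts
#' library-equalized). Under the null of equal per-sample means, the group
#' A total follows the conditional distribution induced by sums of NB
#' variables with sizes proportional to the replicate numbers — binomial
#' splitting when `phi = 0`. The two-sided p-value is the probability-mass
#' rule: the sum of P(s) over all s in 0..T with P(s) <= P(observed),
#' capped at 1. `T = 0` returns p = 1 by convention.
#'
#' @param countsA,countsB per-replicate counts for the two groups.
#' @param phi common NB dispersion (>= 0).
#' @return two-sided p-value.
#' @export
exact_test <- function(countsA, countsB, phi = 0) {
  sA <- sum(countsA); sB <- sum(countsB)
  tot <- sA + sB
  if (tot == 0) return(1)
  nA <- length(countsA); nB <- length(countsB)
  s <- 0:tot
  if (phi <= 0) {
    lw <- stats::dbinom(s, tot, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    lw <- lgamma(s + rA) - lgamma(s + 1) + lgamma(tot - s + rB) - lgamma(tot - s + 1)
  }
  w <- exp(lw - max(lw))
  p_s <- w / sum(w)
  p_obs <- p_s[sA + 1]
  min(1, sum(p_s[p_s <= p_obs * (1 + 1e-12)]))
}

#' Log2 fold change from group-mean abundances
#'
#' `log2((mean2 + pseudocount) / (mean1 + pseudocount))`; group 2 over
#' group 1 (HC over NC in the default pipeline).
#'
#' @param mean1,mean2 non-negative group means (e.g. mean RPKM).
#' @param pseudocount additive stabilizer (default 0.01).
#' @return log2 fold change (vectorized).
#' @export
fold_change <- function(mean1, mean2, pseudocount = 0.01) {
  log2((mean2 + pseudocount) / (mean1 + pseudocount))
}

#' Call differential expression
#'
#' `up` iff `log2fc >= lfc_min` and `p < alpha`; `down` iff
#' `log2fc <= -lfc_min` and `p < alpha`; else `ns`. The fold-change bound
#' is inclusive, the alpha bound exclusive (defaults implement the
#' FC >= 2 & P < 0.05 rule).
#'
#' @param log2fc,pvalue numeric vectors.
#' @param lfc_min minimum |log2 FC| (default 1).
#' @param alpha significance level (default 0.05).
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
call_degs <- function(log2fc, pvalue, lfc_min = 1, alpha = 0.05) {
  ifelse(pvalue < alpha & log2fc >= lfc_min, "up",
         ifelse(pvalue < alpha & log2fc <= -lfc_min, "down", "ns"))
}

#' Two-group differential expression (NB exact test)
#'
#' Full per-assay pipeline: library equalization, common-dispersion
#' estimation, per-gene conditional exact test, RPKM-based fold change and
#' the FC/alpha call. BH-adjusted q-values are reported as an extra
#' column; the calls themselves use raw p-values.
#'
#' @param counts gene x sample count matrix.
#' @param groups two-level factor (level 1 = reference, e.g. NC).
#' @param rpkm_table matching RPKM matrix for fold-change and reporting;
#'   computed from `counts` with `gene_lengths_nt` when omitted.
#' @param gene_lengths_nt per-gene lengths used if `rpkm_table` is NULL.
#' @param lfc_min,alpha,pseudocount calling parameters; see [call_degs()].
#' @param dispersion optional fixed phi; estimated when NULL.
#' @return `data.frame` of class `differential_result`: `gene_id`,
#'   `log2fc`, `pvalue`, `qvalue`, per-group mean RPKM, `call`. The
#'   dispersion estimate is in `attr(, "dispersion")`.
#' @export
differential_expression <- function(counts, groups, rpkm_table = NULL,
                                    gene_lengths_nt = NULL, lfc_min = 1,
                                    alpha = 0.05, pseudocount = 0.01,
                                    dispersion = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop_("groups must have exactly 2 levels")
  if (is.null(rpkm_table)) {
    if (is.null(gene_lengths_nt))
      stop_("supply rpkm_table or gene_lengths_nt")
    rpkm_table <- rpkm(counts, gene_lengths_nt[rownames(counts)])
  }
  eq <- equalize_libraries(counts)
  if (is.null(dispersion)) {
    disp <- estimate_common_dispersion(eq$counts, groups)
  } else {
    disp <- structure(list(phi = dispersion, method = "fixed",
                           n_genes_used = NA_integer_),
                      class = "dispersion_estimate")
  }
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  pv <- vapply(seq_len(nrow(eq$counts)), function(i) {
    exact_test(eq$counts[i, g1], eq$counts[i, g2], disp$phi)
  }, 0)
  m1 <- rowMeans(rpkm_table[, g1, drop = FALSE])
  m2 <- rowMeans(rpkm_table[, g2, drop = FALSE])
  lfc <- fold_change(m1, m2, pseudocount)
  out <- data.frame(gene_id = rownames(counts), log2fc = lfc, pvalue = pv,
                    qvalue = stats::p.adjust(pv, "BH"),
                    mean_rpkm_1 = m1, mean_rpkm_2 = m2,
                    call = call_degs(lfc, pv, lfc_min, alpha),
                    stringsAsFactors = FALSE)
  names(out)[5:6] <- paste0("mean_rpkm_", levels(groups))
  rownames(out) <- NULL
  attr(out, "dispersion") <- disp
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student (pooled-variance) t with `df = n1 + n2 - 2` and a two-tailed
#' p-value, computed from printed means, SDs and group sizes; `welch =
#' TRUE` switches to the Welch-Satterthwaite form. Two identical
#' zero-variance groups give t = 0, p = 1.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics (n >= 2,
#'   sd >= 0).
#' @param welch use Welch's unequal-variance form.
#' @return list of class `summary_ttest`: `t`, `df`, `pvalue`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    df <- se2^2 / (sd1^4 / (n1^2 * (n1 - 1)) + sd2^4 / (n2^2 * (n2 - 1)))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (se == 0) {
    t <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    t <- (mean1 - mean2) / se
  }
  if (is.nan(df)) df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, pvalue = p), class = "summary_ttest")
}
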