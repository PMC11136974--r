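make_rpkm_pair <- function(rna, rfp) {
  colnames(rna) <- colnames(rfp) <- paste0(rep(c("NC_", "HC_"), each = 3), 1:3)
  list(rna = rna, rfp = rfp,
       groups = factor(rep(c("NC", "HC"), each = 3), levels = c("NC", "HC")))
}

test_that("TE is the RFP/RNA RPKM ratio with the eligibility filter", {
  rna <- rbind(g1 = rep(10, 6), g2 = rep(0.01, 6), g3 = rep(4, 6))
  rfp <- rbind(g1 = rep(20, 6), g2 = rep(5, 6), g3 = rep(4, 6))
  x <- make_rpkm_pair(rna, rfp)
  te <- compute_te(x$rna, x$rfp, x$groups)
  expect_equal(unname(te$te["g1", 1]), 2)
  expect_equal(unname(te$log2_te["g1", 1]), 1)
  expect_false(te$eligible[["g2"]])  # RNA below min_rpkm in both groups
  expect_equal(unname(te$log2_te["g3", ]), rep(0, 6), ignore_attr = TRUE)

  # zero RNA in one sample leaves the gene with its other samples
  rna2 <- rna; rna2["g1", 2] <- 0
  te2 <- compute_te(rna2, x$rfp, x$groups)
  expect_true(is.na(te2$te["g1", 2]))
  expect_equal(unname(te2$te["g1", 1]), 2)
})

test_that("differential TE calls planted shifts and skips thin genes", {
  set.seed(12)
  noise <- matrix(rnorm(18, 0, 0.02), 3, 6)
  rna <- matrix(10 * 2^noise, 3, 6,
                dimnames = list(c("flat", "shift", "thin"), NULL))
  rfp <- rna
  rfp["shift", 4:6] <- rna["shift", 4:6] * 4  # planted TE shift +2
  rna["thin", c(1, 2, 4, 5)] <- 0             # <2 defined TE values/group
  x <- make_rpkm_pair(rna, rfp)
  te <- compute_te(x$rna, x$rfp, x$groups)
  dte <- diff_te(te)
  expect_equal(dte$call[dte$gene_id == "shift"], "up")
  expect_equal(dte$call[dte$gene_id == "flat"], "ns")
  expect_false("thin" %in% dte$gene_id)
  expect_equal(attr(dte, "n_skipped"), 1L)
})

test_that("nine-quadrant classification follows the 3x3 letter grid", {
  de <- function(gene, lfc, p) data.frame(
    gene_id = gene, log2fc = lfc, pvalue = p,
    call = call_degs(lfc, p), stringsAsFactors = FALSE)
  txn <- de(c("b", "e", "g", "x"), c(0.2, 0.1, -1.2, 2), c(0.8, 0.9, 0.001, 0.001))
  trans <- de(c("b", "e", "g"), c(1.5, 0, -1.3), c(0.01, 0.5, 0.002))
  quad <- quadrant_classify(txn, trans)
  expect_equal(quad$quadrant[match(c("b", "e", "g"), quad$gene_id)],
               c("B", "E", "G"))
  expect_equal(attr(quad, "n_missing"), 1L)  # "x" absent from trans
  # total partition over the shared universe
  expect_equal(nrow(quad), 3)
  expect_true(all(quad$quadrant %in% LETTERS[1:9]))
  expect_equal(translation_only_set(quad), "b")
  expect_equal(length(intersect(translation_only_set(quad),
                                transcription_only_set(quad))), 0)
})

test_that("quadrant census is a total partition on simulated data", {
  s <- simulate_counts(sim_design(n_genes = 200, seed = 13))
  len <- stats::setNames(rep(1000, 200), rownames(s$rna))
  de_rna <- differential_expression(s$rna, s$groups, gene_lengths_nt = len)
  de_rfp <- differential_expression(s$rfp, s$groups, gene_lengths_nt = len)
  quad <- quadrant_classify(de_rna, de_rfp)
  census <- table(factor(quad$quadrant, levels = LETTERS[1:9]))
  expect_equal(sum(census), nrow(quad))
  expect_equal(sort(unique(c(translation_only_set(quad),
                             transcription_only_set(quad)))),
               sort(quad$gene_id[quad$quadrant %in% c("B", "D", "F", "H")]))
})

test_that("TE type-I error is controlled on null data", {
  s <- null_simulation(n_genes = 2000, phi = 0.05, seed = 14)
  len <- stats::setNames(rep(1000, 2000), rownames(s$rna))
  rr <- rpkm(s$rna, len); rf <- rpkm(s$rfp, len)
  te <- compute_te(rr, rf, s$groups)
  dte <- diff_te(te)
  expect_lte(mean(dte$pvalue < 0.05), 0.07)
})

test_that("OLS regression matches exact lines and null correlation", {
  x <- c(1, 2, 3, 4, 5)
  f1 <- fit_regression(x, x)
  expect_equal(f1$slope, 1); expect_equal(f1$r_squared, 1)
  f2 <- fit_regression(x, 2 * x + 1)
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 1)
  expect_equal(f2$r_squared, 1)
  set.seed(15)
  f3 <- fit_regression(rnorm(10000), rnorm(10000))
  expect_lt(f3$r_squared, 0.01)
  expect_error(fit_regression(rep(1, 5), x), "zero variance")
})

test_that("Mann-Whitney matches its exact and approximate conventions", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$pvalue, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # identical multisets: ties force the approximation, p = 1
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$pvalue, 1)
  # large planted shift
  set.seed(16)
  mw3 <- mann_whitney(rnorm(50), rnorm(50, 3))
  expect_lt(mw3$pvalue, 0.01)
  # the tie-corrected normal branch equals the standard implementation
  a <- c(1, 2, 2, 5, 7, 9); b <- c(2, 3, 3, 8, 10, 11)
  mw4 <- mann_whitney(a, b, exact_max = 0)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw4$pvalue, ref$p.value, tolerance = 1e-12)
})

test_that("ECDF tables are right-continuous and end at 1", {
  e <- ecdf_table(c(1, 2, 3))
  expect_equal(e$fraction, c(1, 2, 3) / 3)
  e2 <- ecdf_table(rep(7, 5))
  expect_equal(nrow(e2), 1)
  expect_equal(e2$fraction, 1)
  # stochastic dominance: shifted sample's ECDF is pointwise no larger
  set.seed(17)
  x <- rnorm(200); y <- x + 1
  ex <- ecdf_table(x)
  fy <- stats::ecdf(y)
  expect_true(all(fy(ex$value) <= ex$fraction + 1e-12))
})

test_that("globally down-shifted translation lowers mean TE detectably", {
  s <- simulate_counts(sim_design(n_genes = 800, dispersion = 0.02,
                                  effect_props = c(null = 1, txn_only = 0,
                                                   trans_only = 0,
                                                   concordant = 0),
                                  seed = 18))
  len <- stats::setNames(rep(1000, 800), rownames(s$rna))
  rr <- rpkm(s$rna, len)
  # impose a global HC translational down-shift on the counts
  rfp <- s$rfp; rfp[, 4:6] <- matrix(as.integer(round(rfp[, 4:6] * 0.6)), ncol = 3)
  rf <- rpkm(rfp, len, total_mapped = colSums(s$rfp))  # unnormalized depth
  te <- compute_te(rr, rf, s$groups)
  m <- colMeans(te$group_mean_log2_te, na.rm = TRUE)
  expect_lt(m[["HC"]], m[["NC"]])
  fin <- function(v) v[is.finite(v)]
  mw <- mann_whitney(fin(te$group_mean_log2_te[, "NC"]),
                     fin(te$group_mean_log2_te[, "HC"]))
  expect_lt(mw$pvalue, 0.01)
})
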