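test_that("generators are deterministic in the seed", {
  expect_identical(make_annotation(100, seed = 1), make_annotation(100, seed = 1))
  d <- sim_design(n_genes = 50, seed = 3)
  s1 <- simulate_counts(d); s2 <- simulate_counts(d)
  expect_identical(s1$rna, s2$rna)
  expect_identical(s1$rfp, s2$rfp)
  d2 <- sim_design(n_genes = 50, seed = 4)
  expect_false(identical(simulate_counts(d2)$rna, s1$rna))

  ann <- make_annotation(20, seed = 2)
  ab <- stats::setNames(rep(1, 20), ann$gene_id)
  p <- footprint_sim_params(reads_total = 500, seed = 5)
  expect_identical(simulate_footprints(ann, ab, p),
                   simulate_footprints(ann, ab, p))
})

test_that("simulated annotations have in-frame CDS and valid extents", {
  ann <- make_annotation(200, seed = 11)
  expect_equal(nrow(ann), 200)
  expect_true(all((ann$cds_end - ann$cds_start) %% 3 == 0))
  expect_true(all(ann$cds_start >= 0 & ann$cds_start < ann$cds_end &
                  ann$cds_end <= ann$total_length))
  expect_equal(nrow(make_annotation(0, seed = 1)), 0)
})

test_that("truth table respects the planted effect-class invariants", {
  d <- sim_design(n_genes = 400, effect_props = c(null = 0.25, txn_only = 0.25,
                                                  trans_only = 0.25,
                                                  concordant = 0.25),
                  seed = 21)
  tr <- simulate_counts(d)$truth
  expect_equal(unname(table(tr$class)[c("concordant", "null", "trans_only",
                                        "txn_only")]),
               rep(100L, 4), ignore_attr = TRUE)
  with(tr[tr$class == "trans_only", ], {
    expect_true(all(rna_log2fc == 0 & rfp_log2fc != 0))
  })
  with(tr[tr$class == "txn_only", ], {
    expect_true(all(rna_log2fc == rfp_log2fc & te_log2fc == 0))
  })
  with(tr[tr$class == "null", ], {
    expect_true(all(rna_log2fc == 0 & rfp_log2fc == 0))
  })
  # rfp effect decomposes as transcriptional effect + TE shift
  expect_equal(tr$rfp_log2fc, tr$rna_log2fc + tr$te_log2fc)
})

test_that("Poisson branch reproduces the expected mean abundance", {
  # one gene at known relative abundance, phi = 0: the sample mean over
  # many replicate draws must match weight * library size (Poisson oracle)
  d <- sim_design(n_genes = 2, n_per_group = 5000, lib_size_rna = 1e4,
                  dispersion = 0,
                  effect_props = c(null = 1, txn_only = 0, trans_only = 0,
                                   concordant = 0),
                  seed = 31)
  s <- simulate_counts(d)
  expected <- rowMeans(s$rna)  # both groups null: all columns are draws
  # recover the weights from the construction: E[count] = w * L, and
  # w1 + w2 = 1, so E[total per sample] = L
  mu <- expected
  se <- sqrt(mu / ncol(s$rna))
  expect_true(abs(sum(mu) - 1e4) < 3 * sqrt(1e4 / ncol(s$rna)))
  # per-gene means positive and consistent across the two groups
  g1 <- rowMeans(s$rna[, 1:5000]); g2 <- rowMeans(s$rna[, 5001:10000])
  expect_true(all(abs(g1 - g2) < 6 * se))
})

test_that("footprint simulator honors forced length, region and frame", {
  ann <- make_annotation(30, seed = 41)
  ab <- stats::setNames(rep(1, 30), ann$gene_id)
  # point-mass length
  p28 <- footprint_sim_params(length_probs = c("28" = 1), reads_total = 800,
                              seed = 42)
  fp28 <- simulate_footprints(ann, ab, p28)
  expect_true(all(fp28$length == 28))
  # forced CDS + perfect frame fidelity -> downstream frame 0 fraction 1
  pf <- footprint_sim_params(frame_fidelity = 1,
                             region_probs = c(UTR5 = 0, CDS = 1, UTR3 = 0),
                             reads_total = 2000, seed = 43)
  fpf <- simulate_footprints(ann, ab, pf)
  expect_equal(unname(periodicity(fpf, ann)$frame_fractions[["f0"]]), 1.0)
  expect_equal(unname(region_occupancy(fpf, ann)$fractions[["CDS"]]), 1.0)
})

test_that("simulated CDS occupancy matches the requested probability", {
  ann <- make_annotation(100, seed = 51)
  ab <- stats::setNames(rep(1, 100), ann$gene_id)
  p <- footprint_sim_params(region_probs = c(UTR5 = 0.15, CDS = 0.7,
                                             UTR3 = 0.15),
                            reads_total = 50000, seed = 52)
  fp <- simulate_footprints(ann, ab, p)
  occ <- region_occupancy(fp, ann)
  expect_true(abs(occ$fractions[["CDS"]] - 0.7) < 0.02)  # binomial oracle
})

test_that("footprint length histogram converges to the target distribution", {
  ann <- make_annotation(100, seed = 61)
  ab <- stats::setNames(rep(1, 100), ann$gene_id)
  p <- footprint_sim_params(reads_total = 100000, seed = 62)
  fp <- simulate_footprints(ann, ab, p)
  emp <- table(factor(fp$length, levels = 15:35)) / nrow(fp)
  tv <- 0.5 * sum(abs(as.numeric(emp) - default_length_probs()))
  expect_lt(tv, 0.02)
  expect_true(length_histogram(fp)$modal_length %in% 27:32)
})

test_that("truth table round-trips through the writer", {
  s <- simulate_counts(sim_design(n_genes = 10, seed = 71))
  path <- tempfile(fileext = ".tsv")
  write_truth(s$truth, path)
  expect_equal(length(readLines(path)), 11)
  back <- read_table_tsv(path)
  expect_equal(back$class, s$truth$class)
  expect_equal(back$te_log2fc, s$truth$te_log2fc, tolerance = 1e-6)
})
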