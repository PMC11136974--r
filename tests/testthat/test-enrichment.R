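test_that("ORA reproduces the hypergeometric tail by direct summation", {
  set.seed(31)
  universe <- paste0("g", 1:60)
  sets <- list(
    setA = sample(universe, 12),
    setB = sample(universe, 25),
    setC = sample(universe, 5))
  study <- sample(universe, 15)
  res <- ora(study, universe, sets, min_overlap = 0)
  for (i in seq_len(nrow(res))) {
    K <- res$K[i]; k <- res$k[i]; n <- res$n[i]; N <- res$N[i]
    # direct summation over the hypergeometric mass
    manual <- sum(vapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j), 0)) / choose(N, n)
    expect_equal(res$pvalue[i], manual, tolerance = 1e-10)
  }
  # worked case: 5 study genes, all in a 10-member set, universe 210
  u2 <- paste0("u", 1:210)
  s2 <- list(hit = u2[1:10])
  r2 <- ora(u2[1:5], u2, s2)
  expect_equal(r2$pvalue,
    stats::phyper(4, 10, 200, 5, lower.tail = FALSE), tolerance = 1e-14)
  expect_equal(r2$k, 5L, ignore_attr = TRUE)
})

test_that("ORA validates its inputs and handles empty overlap", {
  universe <- paste0("g", 1:20)
  sets <- list(s1 = universe[1:5])
  expect_error(ora(c("g1", "not_there"), universe, sets), "not_there")
  # no overlap at min_overlap 1: empty result with the full column set
  r <- ora("g10", universe, list(s1 = universe[1:5]))
  expect_equal(nrow(r), 0)
  expect_true(all(c("set_name", "pvalue", "qvalue") %in% names(r)))
  # duplicated study genes collapse
  r2 <- ora(c("g1", "g1", "g2"), universe, sets)
  expect_equal(r2$n, 2L, ignore_attr = TRUE)
  # BH q-values never drop below the raw p-values' minimum pattern
  set.seed(32)
  big <- lapply(1:8, function(i) sample(universe, 6))
  names(big) <- paste0("s", 1:8)
  r3 <- ora(universe[1:6], universe, big, min_overlap = 0)
  expect_true(all(r3$qvalue >= r3$pvalue - 1e-12))
  expect_equal(r3$qvalue, stats::p.adjust(r3$pvalue, "BH"))
})

test_that("gene ranking orders by score with deterministic tie breaks", {
  expr <- rbind(up = c(1, 1, 1, 8, 8, 8),
                dn = c(9, 9, 9, 2, 2, 2),
                t1 = c(5, 5, 5, 5, 5, 5),
                t2 = c(4, 4, 4, 4, 4, 4))
  colnames(expr) <- paste0("s", 1:6)
  groups <- factor(rep(c("NC", "HC"), each = 3), levels = c("NC", "HC"))
  rk <- rank_genes(expr, groups)
  expect_equal(rk$gene_id[1], "up")
  expect_equal(rk$gene_id[4], "dn")
  # zero-variance rows fall back to the sd floor 0.2 * |mean|
  expect_equal(rk$score[rk$gene_id == "up"],
               (8 - 1) / (0.2 * 8 + 0.2 * 1), tolerance = 1e-12)
  # tied scores break by gene id
  expect_equal(rk$gene_id[2:3], c("t1", "t2"))
  # log2fc metric matches fold_change on the group means
  rk2 <- rank_genes(expr, groups, metric = "log2fc")
  expect_equal(rk2$score[rk2$gene_id == "up"],
               fold_change(1, 8), tolerance = 1e-12)
  expect_error(rank_genes(expr[, c(1, 4)], groups[c(1, 4)]),
               ">= 2 samples")
})

test_that("GSEA enrichment score matches a brute-force running sum", {
  brute_es <- function(ranked, members, p) {
    hit <- ranked$gene_id %in% members
    N <- nrow(ranked); K <- sum(hit)
    nr <- sum(abs(ranked$score[hit])^p)
    run <- 0; best <- 0
    for (i in seq_len(N)) {
      run <- run + if (hit[i]) abs(ranked$score[i])^p / nr else -1 / (N - K)
      if (abs(run) > abs(best)) best <- run
    }
    best
  }
  set.seed(41)
  for (rep in 1:5) {
    N <- sample(20:200, 1)
    ranked <- data.frame(gene_id = paste0("g", 1:N),
                         score = sort(rnorm(N), decreasing = TRUE),
                         stringsAsFactors = FALSE)
    members <- sample(ranked$gene_id, sample(3:10, 1))
    for (p in c(0, 1))
      expect_equal(gsea_es(ranked, members, p),
                   brute_es(ranked, members, p), tolerance = 1e-12)
  }
  # worked cases: 3-gene list with the top gene as sole member
  r3 <- data.frame(gene_id = c("a", "b", "c"), score = c(3, 2, 1))
  expect_equal(gsea_es(r3, "a"), 1)
  expect_equal(gsea_es(r3, "a", p = 0), 1)
  # member at the bottom: the extreme deviation is negative
  expect_equal(gsea_es(r3, "c", p = 0), -1)
  expect_error(gsea_es(r3, "zzz"), "no gene-set member")
})

test_that("reversing the ranking negates an unweighted enrichment score", {
  set.seed(42)
  N <- 80
  ranked <- data.frame(gene_id = paste0("g", 1:N),
                       score = sort(rnorm(N), decreasing = TRUE),
                       stringsAsFactors = FALSE)
  members <- sample(ranked$gene_id, 7)
  flipped <- ranked[N:1, ]
  # p = 0: pure KS statistic, symmetric under list reversal (generic sets
  # have a unique extreme deviation)
  expect_equal(gsea_es(flipped, members, p = 0),
               -gsea_es(ranked, members, p = 0), tolerance = 1e-12)
})

test_that("GSEA permutation p-values are deterministic and calibrated", {
  set.seed(43)
  N <- 100
  ranked <- data.frame(gene_id = paste0("g", 1:N),
                       score = sort(rnorm(N), decreasing = TRUE),
                       stringsAsFactors = FALSE)
  # a set made of the top genes: smallest attainable p at this n_perm
  r1 <- gsea_null(ranked, ranked$gene_id[1:8], n_perm = 200, seed = 7)
  expect_equal(r1$pvalue, 1 / 201, tolerance = 1e-12)
  expect_gt(r1$es, 0.9)
  expect_gt(r1$nes, 1)
  # determinism
  r2 <- gsea_null(ranked, ranked$gene_id[1:8], n_perm = 200, seed = 7)
  expect_identical(r1, r2)
  expect_error(gsea_null(ranked, ranked$gene_id[1:8], n_perm = 50), ">= 100")
  expect_error(gsea_null(ranked, ranked$gene_id), "whole ranked list")
})

test_that("gsea over a collection filters by size and sorts by p", {
  set.seed(44)
  N <- 60
  ranked <- data.frame(gene_id = paste0("g", 1:N),
                       score = sort(rnorm(N), decreasing = TRUE),
                       stringsAsFactors = FALSE)
  coll <- list(top = ranked$gene_id[1:6],
               tiny = ranked$gene_id[1:2],        # below min_size
               random = ranked$gene_id[c(5, 20, 35, 50)])
  res <- gsea(ranked, coll, n_perm = 100, seed = 9)
  expect_false("tiny" %in% res$set_name)
  expect_equal(res$set_name[1], "top")
  expect_true(all(diff(res$pvalue) >= 0))
})
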