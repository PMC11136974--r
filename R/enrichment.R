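#' Over-representation analysis (hypergeometric)
#'
#' For each gene set, members are first intersected with the universe
#' (size N); with a study list of size n and K universe members of the
#' set, the enrichment p-value is the hypergeometric upper tail
#' P(X >= k) for the observed overlap k. Enrichment only (no depletion
#' tail); BH q-values are computed across tested sets.
#'
#' @param study character vector of study genes (must be a subset of
#'   `universe`).
#' @param universe character vector, the gene universe.
#' @param collection a [read_gmt()] `gene_set_collection` (or a named list
#'   of character vectors).
#' @param min_overlap sets with overlap below this are skipped
#'   (default 1).
#' @return `data.frame` of class `ora_result`, sorted by p-value:
#'   `set_name`, `k` (overlap), `K` (set size in universe), `n`, `N`,
#'   `pvalue`, `qvalue`, `overlap_genes` (comma-separated).
#' @export
ora <- function(study, universe, collection, min_overlap = 1) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  study <- unique(study); universe <- unique(universe)
  bad <- setdiff(study, universe)
  if (length(bad))
    stop_("study genes not in universe: ",
          paste(head(bad, 5), collapse = ", "),
          if (length(bad) > 5) paste0(" (+", length(bad) - 5, " more)") else "")
  N <- length(universe); n <- length(study)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    hits <- intersect(study, members)
    k <- length(hits)
    if (k < min_overlap) return(NULL)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               pvalue = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE)
  out$qvalue <- stats::p.adjust(out$pvalue, "BH")
  out <- out[order(out$pvalue, out$set_name),
             c("set_name", "k", "K", "n", "N", "pvalue", "qvalue",
               "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Rank genes between two phenotypes
#'
#' Signal-to-noise: `(mean2 - mean1) / (sd2' + sd1')` with each sd floored
#' at 0.2 x |mean| (and at 0.2 when the mean is 0), following the GSEA
#' convention; or a pseudocounted log2 fold change of group means. Ties
#' are broken by gene id for a deterministic order.
#'
#' @param expr gene x sample abundance matrix (e.g. RPKM).
#' @param groups two-level factor; scores are group 2 relative to group 1.
#' @param metric `"signal_to_noise"` (needs >= 2 samples per group) or
#'   `"log2fc"`.
#' @param pseudocount used by the `log2fc` metric.
#' @return `data.frame` with `gene_id`, `score`, ordered by decreasing
#'   score.
#' @export
rank_genes <- function(expr, groups, metric = c("signal_to_noise", "log2fc"),
                       pseudocount = 0.01) {
  metric <- match.arg(metric)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop_("groups must have exactly 2 levels")
  g1 <- groups == levels(groups)[1]; g2 <- groups == levels(groups)[2]
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  if (metric == "signal_to_noise") {
    if (sum(g1) < 2 || sum(g2) < 2)
      stop_("signal_to_noise needs >= 2 samples per group")
    floor_sd <- function(s, m) {
      s <- pmax(s, 0.2 * abs(m))
      ifelse(s == 0, 0.2, s)
    }
    s1 <- floor_sd(apply(expr[, g1, drop = FALSE], 1, stats::sd), m1)
    s2 <- floor_sd(apply(expr[, g2, drop = FALSE], 1, stats::sd), m2)
    score <- (m2 - m1) / (s2 + s1)
  } else {
    score <- fold_change(m1, m2, pseudocount)
  }
  ids <- rownames(expr)
  o <- order(-score, ids)
  data.frame(gene_id = ids[o], score = score[o], stringsAsFactors = FALSE)
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked list; at a member ("hit") the running sum increases by
#' `|score|^p / sum_hits |score|^p`, at a non-member it decreases by
#' `1 / (N - K)`. The enrichment score is the extreme (largest-magnitude)
#' deviation from zero. `p = 1` is the GSEA weighted statistic; `p = 0`
#' gives the classic Kolmogorov-Smirnov form.
#'
#' @param ranked `data.frame` from [rank_genes()] (`gene_id`, `score`).
#' @param members character vector, the gene set.
#' @param p hit weight exponent (default 1).
#' @return enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, members, p = 1) {
  hit <- ranked$gene_id %in% members
  N <- nrow(ranked); K <- sum(hit)
  if (K == 0) stop_("no gene-set member present in the ranked list")
  w <- abs(ranked$score)^p
  nr <- sum(w[hit])
  inc <- if (nr > 0) w * hit / nr else hit / K
  dec <- if (N > K) (!hit) / (N - K) else rep(0, N)
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}

#' GSEA significance by gene-set permutation
#'
#' The null distribution of the enrichment score is built from random
#' member sets of the same size drawn from the ranked universe
#' (phenotype permutation is not useful at n = 3 per group, where only 20
#' label splits exist). `p = (1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`;
#' the normalized score NES divides ES by the mean |null ES| of the
#' matching sign side.
#'
#' @param ranked `data.frame` from [rank_genes()].
#' @param members character vector, the gene set (must not cover the whole
#'   list).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (deterministic result).
#' @param weight hit weight exponent passed to [gsea_es()].
#' @return list of class `enrichment_score`: `es`, `nes`, `pvalue`,
#'   `n_permutations`, `seed`.
#' @export
gsea_null <- function(ranked, members, n_perm = 1000, seed = 1, weight = 1) {
  if (n_perm < 100) stop_("n_perm must be >= 100")
  hit <- ranked$gene_id %in% members
  K <- sum(hit); N <- nrow(ranked)
  if (K >= N) stop_("gene set covers the whole ranked list")
  es <- gsea_es(ranked, members, weight)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gsea_es(ranked, ranked$gene_id[sample.int(N, K)], weight)
    }, 0)
  })
  pval <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  same_side <- null_es[sign(null_es) == sign(es)]
  denom <- if (length(same_side)) mean(abs(same_side)) else mean(abs(null_es))
  structure(list(es = es, nes = if (denom > 0) es / denom else 0,
                 pvalue = pval, n_permutations = n_perm, seed = seed),
            class = "enrichment_score")
}

#' GSEA over a gene-set collection
#'
#' Runs [gsea_es()] + [gsea_null()] for each set in the collection with at
#' least `min_size` members in the ranked list.
#'
#' @inheritParams gsea_null
#' @param collection a `gene_set_collection` or named list.
#' @param min_size minimum members present in the ranked list (default 3).
#' @return `data.frame` sorted by p-value: `set_name`, `size`, `es`,
#'   `nes`, `pvalue`.
#' @export
gsea <- function(ranked, collection, n_perm = 1000, seed = 1, weight = 1,
                 min_size = 3) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  rows <- lapply(names(sets), function(nm) {
    k <- sum(ranked$gene_id %in% sets[[nm]])
    if (k < min_size || k >= nrow(ranked)) return(NULL)
    r <- gsea_null(ranked, sets[[nm]], n_perm = n_perm, seed = seed,
                   weight = weight)
    data.frame(set_name = nm, size = k, es = r$es, nes = r$nes,
               pvalue = r$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), size = integer(),
                      es = numeric(), nes = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$pvalue, out$set_name), ]
  rownames(out) <- NULL
  out
}
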