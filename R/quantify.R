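#' Gene-level counting of footprint records
#'
#' Each record increments exactly one gene — its transcript's gene — iff
#' its assignment point lies inside the counting region; counts for
#' different splice variants of the same gene are combined. The assignment
#' point is the inferred P-site for RFP records and the fragment midpoint
#' for RNA records (RNA fragments have no P-site).
#'
#' @param records footprint `data.frame` for one sample (single assay).
#' @param annotation `transcript_annotation`.
#' @param counting_region `"cds"` (default for RFP) or
#'   `"full_transcript"` (default for RNA).
#' @param offset_table,default_offset P-site offsets (RFP only); see
#'   [psite_position()].
#' @return named integer vector over all genes in the annotation (zeros
#'   for genes without assigned records).
#' @export
count_per_gene <- function(records, annotation,
                           counting_region = c("cds", "full_transcript"),
                           offset_table = NULL, default_offset = 12) {
  counting_region <- match.arg(counting_region)
  genes <- unique(annotation$gene_id)
  if (nrow(records) == 0)
    return(stats::setNames(integer(length(genes)), genes))
  assay <- records$assay %||% rep("RFP", nrow(records))
  is_rna <- assay == "RNA"
  pt <- integer(nrow(records))
  if (any(!is_rna))
    pt[!is_rna] <- psite_position(records[!is_rna, , drop = FALSE],
                                  annotation, offset_table, default_offset)
  if (any(is_rna))
    pt[is_rna] <- records$start[is_rna] + records$length[is_rna] %/% 2L
  idx <- match(records$transcript_id, annotation$transcript_id)
  keep <- !is.na(idx) & !is.na(pt)
  idx <- idx[keep]; pt <- pt[keep]
  lo <- if (counting_region == "cds") annotation$cds_start[idx] else 0L
  hi <- if (counting_region == "cds") annotation$cds_end[idx]
        else annotation$total_length[idx]
  inreg <- pt >= lo & pt < hi
  tab <- table(factor(annotation$gene_id[idx[inreg]], levels = genes))
  stats::setNames(as.integer(tab), genes)
}

#' Per-gene lengths for RPKM
#'
#' For multi-isoform genes the longest isoform's region length is used.
#'
#' @param annotation `transcript_annotation`.
#' @param region `"cds"` or `"full_transcript"`.
#' @return named integer vector of lengths (nt) per gene.
#' @export
gene_lengths <- function(annotation, region = c("cds", "full_transcript")) {
  region <- match.arg(region)
  len <- if (region == "cds") annotation$cds_end - annotation$cds_start
         else annotation$total_length
  out <- tapply(len, annotation$gene_id, max)
  genes <- unique(annotation$gene_id)
  stats::setNames(as.integer(out[genes]), genes)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length/1000) * (total_mapped/1e6))`.
#'
#' @param counts per-gene counts (vector or gene x sample matrix).
#' @param lengths_nt per-gene feature lengths (nt), recycled over columns.
#' @param total_mapped mapped-read total(s): scalar, or one per column
#'   (defaults to column sums for a matrix, `sum(counts)` for a vector).
#' @return RPKM values with the shape of `counts`.
#' @export
rpkm <- function(counts, lengths_nt, total_mapped = NULL) {
  if (any(lengths_nt <= 0)) stop_("gene lengths must be positive")
  if (is.matrix(counts)) {
    if (is.null(total_mapped)) total_mapped <- colSums(counts)
    if (any(total_mapped <= 0)) stop_("total_mapped must be positive")
    sweep(counts / (lengths_nt / 1000), 2, total_mapped / 1e6, "/")
  } else {
    if (is.null(total_mapped)) total_mapped <- sum(counts)
    if (total_mapped <= 0) stop_("total_mapped must be positive")
    counts / ((lengths_nt / 1000) * (total_mapped / 1e6))
  }
}

#' Detected-gene overlap between RNA and RFP
#'
#' A gene is detected in an assay/group iff its raw count reaches
#' `min_count` in at least one replicate of that group; the Venn triple
#' over the two assays is returned.
#'
#' @param rna_counts,rfp_counts gene x sample count matrices on a matched
#'   gene universe.
#' @param groups factor of group labels per sample (same for both assays).
#' @param group the group to evaluate.
#' @param min_count detection threshold (default 1).
#' @return named integer vector `c(n_rna_only, n_rfp_only, n_both)`.
#' @export
detected_overlap <- function(rna_counts, rfp_counts, groups, group,
                             min_count = 1) {
  stopifnot(identical(rownames(rna_counts), rownames(rfp_counts)))
  sel <- groups == group
  det <- function(m) rowSums(m[, sel, drop = FALSE] >= min_count) > 0
  rna <- det(rna_counts); rfp <- det(rfp_counts)
  c(n_rna_only = sum(rna & !rfp), n_rfp_only = sum(!rna & rfp),
    n_both = sum(rna & rfp))
}

#' Histogram of log10 mean abundance over detected genes
#'
#' Group-mean RPKM per gene; zero-mean genes are excluded; fixed bin width
#' 0.25 on the log10 scale.
#'
#' @param rpkm_table gene x sample RPKM matrix.
#' @param groups factor of group labels per sample.
#' @param group group to summarize.
#' @param binwidth bin width in log10 units.
#' @return `data.frame` with `bin_lower`, `bin_upper`, `count`.
#' @export
abundance_distribution <- function(rpkm_table, groups, group,
                                   binwidth = 0.25) {
  mu <- rowMeans(rpkm_table[, groups == group, drop = FALSE])
  x <- log10(mu[mu > 0])
  if (!length(x)) {
    warn_("no genes with nonzero mean abundance")
    return(data.frame(bin_lower = numeric(), bin_upper = numeric(),
                      count = integer()))
  }
  lo <- floor(min(x) / binwidth) * binwidth
  hi <- ceiling(max(x) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  n_bins <- round((hi - lo) / binwidth)
  idx <- pmin(n_bins, floor((x - lo) / binwidth) + 1)  # bins [lower, upper)
  data.frame(bin_lower = lo + binwidth * (seq_len(n_bins) - 1),
             bin_upper = lo + binwidth * seq_len(n_bins),
             count = tabulate(idx, n_bins))
}

#' Sample PCA on log-transformed abundance
#'
#' Input is `log2(RPKM + 1)`; genes are centered (no scaling) and
#' components come from the singular value decomposition, so
#' variance-explained is non-increasing.
#'
#' @param rpkm_table gene x sample RPKM matrix, or a named list of such
#'   matrices (rows are stacked with assay-prefixed gene ids).
#' @param n_components number of components to return.
#' @return list of class `sample_pca`: `coords` (sample x PC matrix) and
#'   `var_explained` (fractions).
#' @export
pca_samples <- function(rpkm_table, n_components = 2) {
  if (is.list(rpkm_table) && !is.data.frame(rpkm_table)) {
    mats <- Map(function(m, nm) {
      rownames(m) <- paste(nm, rownames(m), sep = ":"); m
    }, rpkm_table, names(rpkm_table) %||% seq_along(rpkm_table))
    rpkm_table <- do.call(rbind, mats)
  }
  if (ncol(rpkm_table) < 2) stop_("PCA needs at least 2 samples")
  x <- log2(as.matrix(rpkm_table) + 1)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)]),
            class = "sample_pca")
}
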