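#' Filter raw reads on base quality and N content
#'
#' A read is rejected when strictly more than `max_lowq_frac` of its bases
#' fall below `quality_threshold` (Phred), or strictly more than
#' `max_n_frac` of its bases are N. The tally records the first matching
#' reason (low quality checked first).
#'
#' @param reads `data.frame` from [read_fastq()] (`sequence`, `quality`).
#' @param quality_threshold Phred score below which a base counts as low
#'   quality (default 20).
#' @param max_lowq_frac,max_n_frac rejection fractions (defaults 0.5 and
#'   0.1; both rules are strict "more than").
#' @return list: `kept` (the surviving rows), `rejected` (named counts for
#'   `low_quality` and `n_content`).
#' @export
filter_reads <- function(reads, quality_threshold = 20,
                         max_lowq_frac = 0.5, max_n_frac = 0.1) {
  stopifnot(max_lowq_frac >= 0, max_lowq_frac <= 1,
            max_n_frac >= 0, max_n_frac <= 1)
  n <- nrow(reads)
  if (n == 0)
    return(list(kept = reads, rejected = c(low_quality = 0L, n_content = 0L)))
  lowq <- vapply(phred_scores(reads$quality),
                 function(q) mean(q < quality_threshold), 0)
  nfrac <- vapply(strsplit(toupper(reads$sequence), ""),
                  function(s) mean(s == "N"), 0)
  rej_q <- lowq > max_lowq_frac
  rej_n <- !rej_q & nfrac > max_n_frac
  kept <- reads[!(rej_q | rej_n), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       rejected = c(low_quality = sum(rej_q), n_content = sum(rej_n)))
}

#' Retain footprints within a length window
#'
#' Inclusive at both ends: the defaults keep 15-35 nt records.
#'
#' @param records footprint `data.frame`.
#' @param min_len,max_len inclusive bounds (nt).
#' @return the retained rows.
#' @export
length_filter <- function(records, min_len = 15, max_len = 35) {
  out <- records[records$length >= min_len & records$length <= max_len, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer P-site positions
#'
#' P-site = read start + a 5'-end offset, by default a single global 12 nt
#' (standard for 27-32 nt footprints), overridable per read length via
#' `offset_table`. Positions beyond the transcript are `NA` (excluded from
#' P-site analyses) when an annotation is supplied.
#'
#' @param records footprint `data.frame`.
#' @param annotation optional `transcript_annotation` for bounds checking.
#' @param offset_table optional named numeric, length (nt) -> offset (nt).
#' @param default_offset offset for lengths absent from `offset_table`.
#' @return integer vector of 0-based P-site positions (NA = excluded).
#' @export
psite_position <- function(records, annotation = NULL, offset_table = NULL,
                           default_offset = 12) {
  off <- rep(as.integer(default_offset), nrow(records))
  if (!is.null(offset_table)) {
    m <- match(as.character(records$length), names(offset_table))
    off[!is.na(m)] <- as.integer(offset_table[m[!is.na(m)]])
  }
  p <- records$start + off
  if (!is.null(annotation)) {
    total <- annotation$total_length[match(records$transcript_id,
                                           annotation$transcript_id)]
    p[is.na(total) | p >= total | p < 0] <- NA_integer_
  }
  p
}

# Attach P-site and transcript-model columns; drops records whose P-site
# cannot be placed. Shared by the QC and counting operations.
psite_frame_df <- function(records, annotation, offset_table = NULL,
                           default_offset = 12) {
  p <- psite_position(records, annotation, offset_table, default_offset)
  idx <- match(records$transcript_id, annotation$transcript_id)
  keep <- !is.na(p) & !is.na(idx)
  data.frame(gene_id = annotation$gene_id[idx[keep]],
             psite = p[keep],
             cds_start = annotation$cds_start[idx[keep]],
             cds_end = annotation$cds_end[idx[keep]],
             total_length = annotation$total_length[idx[keep]],
             frame_ok = annotation$frame_ok[idx[keep]],
             stringsAsFactors = FALSE)
}

#' Footprint length histogram
#'
#' Exact length counts with the modal length; ties break toward the
#' smaller length for a deterministic mode.
#'
#' @param records footprint `data.frame`.
#' @return list of class `length_histogram`: `counts` (named by length,
#'   ascending) and `modal_length`.
#' @export
length_histogram <- function(records) {
  if (nrow(records) == 0)
    return(structure(list(counts = integer(0), modal_length = NA_integer_),
                     class = "length_histogram"))
  tab <- table(records$length)
  lens <- as.integer(names(tab))
  o <- order(lens)
  counts <- stats::setNames(as.integer(tab)[o], lens[o])
  structure(list(counts = counts,
                 modal_length = as.integer(names(counts)[which.max(counts)])),
            class = "length_histogram")
}

# Region of a P-site under the half-open convention:
# p < cds_start -> UTR5; cds_start <= p < cds_end -> CDS; p >= cds_end -> UTR3.
psite_region <- function(psite, cds_start, cds_end) {
  ifelse(psite < cds_start, "UTR5", ifelse(psite < cds_end, "CDS", "UTR3"))
}

#' Fraction of P-sites in 5'UTR, CDS and 3'UTR
#'
#' Each record is assigned to exactly one region by its P-site under the
#' half-open CDS convention; fractions are counts over total assigned
#' records and sum to 1.
#'
#' @inheritParams psite_position
#' @param annotation `transcript_annotation`.
#' @return list of class `region_occupancy`: `fractions` (named UTR5, CDS,
#'   UTR3), `n` records used.
#' @export
region_occupancy <- function(records, annotation, offset_table = NULL,
                             default_offset = 12) {
  df <- psite_frame_df(records, annotation, offset_table, default_offset)
  if (nrow(df) == 0) stop_("no records with an assignable P-site")
  reg <- factor(psite_region(df$psite, df$cds_start, df$cds_end),
                levels = c("UTR5", "CDS", "UTR3"))
  counts <- table(reg)
  fr <- stats::setNames(as.vector(counts) / nrow(df), names(counts))
  structure(list(fractions = fr, n = nrow(df)), class = "region_occupancy")
}

#' Metagene profile around the start or stop codon
#'
#' P-site counts by offset from the anchor: the first base of the start
#' codon (`cds_start`) or the first base of the stop codon
#' (`cds_end - 3`), so that frame-0 offsets align at both anchors.
#' Offsets outside `[-window, window]` are ignored; counts are summed over
#' transcripts.
#'
#' @inheritParams region_occupancy
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param window half-width in nt (>= 3).
#' @return list of class `metagene_profile`: `anchor`, `counts` (named by
#'   offset, covering the full window).
#' @export
metagene_profile <- function(records, annotation,
                             anchor = c("start_codon", "stop_codon"),
                             window = 30, offset_table = NULL,
                             default_offset = 12) {
  anchor <- match.arg(anchor)
  if (window < 3) stop_("window must be >= 3")
  df <- psite_frame_df(records, annotation, offset_table, default_offset)
  a <- if (anchor == "start_codon") df$cds_start else df$cds_end - 3L
  offs <- df$psite - a
  offs <- offs[offs >= -window & offs <= window]
  grid <- seq.int(-window, window)
  counts <- stats::setNames(tabulate(match(offs, grid), length(grid)), grid)
  structure(list(anchor = anchor, counts = counts),
            class = "metagene_profile")
}

#' Three-nucleotide periodicity of CDS P-sites
#'
#' Frame of a P-site = (position - cds_start) mod 3, over all P-sites
#' falling inside a frame-clean CDS. A strong excess of frame 0 is the
#' hallmark of genuine ribosome footprints.
#'
#' @inheritParams region_occupancy
#' @return list of class `periodicity_result`: `frame_fractions` (f0, f1,
#'   f2, summing to 1) and `n_psites`.
#' @export
periodicity <- function(records, annotation, offset_table = NULL,
                        default_offset = 12) {
  df <- psite_frame_df(records, annotation, offset_table, default_offset)
  df <- df[df$frame_ok & df$psite >= df$cds_start & df$psite < df$cds_end, ,
           drop = FALSE]
  if (nrow(df) == 0) stop_("no CDS P-sites available for periodicity")
  fr <- (df$psite - df$cds_start) %% 3L
  counts <- tabulate(fr + 1L, 3L)
  structure(list(frame_fractions = stats::setNames(counts / sum(counts),
                                                   c("f0", "f1", "f2")),
                 n_psites = nrow(df)),
            class = "periodicity_result")
}
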