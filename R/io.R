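#' Read a transcript annotation
#'
#' Reads transcript models (gene id, transcript id, total length, CDS
#' extent) from either the native TSV dialect or a minimal GTF subset with
#' single-exon transcript-space records. Coordinates are 0-based half-open
#' in transcript space.
#'
#' A CDS whose length is not a multiple of 3 is kept but flagged
#' (`frame_ok = FALSE`) and excluded from reading-frame analyses.
#'
#' @param path file path.
#' @param dialect `"tsv"` (header `gene_id`, `transcript_id`,
#'   `total_length`, `cds_start`, `cds_end`) or `"gtf_subset"`.
#' @return A `data.frame` of class `transcript_annotation` with columns
#'   `gene_id`, `transcript_id`, `total_length`, `cds_start`, `cds_end`,
#'   `frame_ok`.
#' @export
read_annotation <- function(path, dialect = c("tsv", "gtf_subset")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("annotation file not found: ", path)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    required <- c("gene_id", "transcript_id", "total_length", "cds_start", "cds_end")
    if (nrow(df) == 0 && !all(required %in% names(df))) {
      warn_("empty annotation file: ", path)
      return(validate_annotation(empty_annotation()))
    }
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop_("annotation TSV missing column(s): ", paste(missing, collapse = ", "))
    if (nrow(df) == 0) warn_("annotation file has no records: ", path)
    df <- df[required]
  } else {
    df <- parse_gtf_subset(path)
  }
  validate_annotation(df)
}

empty_annotation <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             total_length = integer(), cds_start = integer(),
             cds_end = integer(), stringsAsFactors = FALSE)
}

# Core invariant checks shared by the readers and the simulator.
validate_annotation <- function(df) {
  df$total_length <- as.integer(df$total_length)
  df$cds_start <- as.integer(df$cds_start)
  df$cds_end <- as.integer(df$cds_end)
  bad <- which(is.na(df$total_length) | is.na(df$cds_start) | is.na(df$cds_end) |
               df$cds_start < 0 | df$cds_start >= df$cds_end |
               df$cds_end > df$total_length)
  if (length(bad))
    stop_("malformed annotation row(s) at line ", paste(bad[1] + 1L),
          ": need 0 <= cds_start < cds_end <= total_length")
  if (anyDuplicated(df$transcript_id))
    stop_("duplicate transcript_id: ",
          paste(unique(df$transcript_id[duplicated(df$transcript_id)]), collapse = ", "))
  df$frame_ok <- (df$cds_end - df$cds_start) %% 3L == 0L
  if (any(!df$frame_ok))
    warn_(sum(!df$frame_ok), " transcript(s) with CDS length not a multiple of 3; ",
          "flagged and excluded from frame analyses")
  rownames(df) <- NULL
  class(df) <- c("transcript_annotation", "data.frame")
  df
}

# Minimal GTF reader: single-exon transcript-space features; the exon row
# carries the transcript extent, the CDS row the coding extent (1-based
# inclusive, converted here to 0-based half-open).
parse_gtf_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    warn_("empty annotation file: ", path)
    return(empty_annotation())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- which(lengths(fields) < 9)
  if (length(n_bad)) stop_("malformed GTF row at line ", n_bad[1])
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  feat <- vapply(fields, `[[`, "", 3)
  start <- as.integer(vapply(fields, `[[`, "", 4))
  end <- as.integer(vapply(fields, `[[`, "", 5))
  attrs <- vapply(fields, `[[`, "", 9)
  tid <- attr_of(attrs, "transcript_id")
  gid <- attr_of(attrs, "gene_id")
  if (anyNA(tid) || anyNA(gid))
    stop_("GTF row missing gene_id/transcript_id at line ",
          which(is.na(tid) | is.na(gid))[1])
  ex <- feat == "exon"
  cds <- feat == "CDS"
  tids <- unique(tid)
  out <- lapply(tids, function(t) {
    e <- which(ex & tid == t); c0 <- which(cds & tid == t)
    if (length(e) != 1 || length(c0) != 1)
      stop_("gtf_subset requires exactly one exon and one CDS feature per ",
            "transcript; violated for ", t)
    data.frame(gene_id = gid[e], transcript_id = t,
               total_length = end[e] - start[e] + 1L,
               cds_start = start[c0] - 1L, cds_end = end[c0],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read aligned footprint / fragment records
#'
#' Reads a transcript-coordinate table of aligned ribosome footprints (or
#' RNA fragments) with columns `transcript_id`, `start` (0-based), `length`
#' and `assay` (`RFP`/`RNA`). When an annotation is supplied, records
#' referencing unknown transcripts — or overhanging their transcript — are
#' dropped with a counted warning (mirrors tolerant read-mapping
#' pipelines).
#'
#' @param path file path.
#' @param annotation optional `transcript_annotation` used to validate
#'   transcript references and extents.
#' @return `data.frame` with columns `transcript_id`, `start`, `length`,
#'   `assay`; the number of dropped records is in `attr(, "n_dropped")`.
#' @export
read_footprints <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop_("footprint file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "start", "length", "assay")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_("footprint TSV missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  df$start <- as.integer(df$start)
  df$length <- as.integer(df$length)
  if (any(df$start < 0, na.rm = TRUE))
    stop_("negative start at line ", which(df$start < 0)[1] + 1L)
  if (any(is.na(df$start) | is.na(df$length) | df$length <= 0))
    stop_("malformed footprint row at line ",
          which(is.na(df$start) | is.na(df$length) | df$length <= 0)[1] + 1L)
  n_dropped <- 0L
  if (!is.null(annotation)) {
    idx <- match(df$transcript_id, annotation$transcript_id)
    total <- annotation$total_length[idx]
    keep <- !is.na(idx) & df$start + df$length <= total
    n_dropped <- sum(!keep)
    if (n_dropped > 0)
      warn_(n_dropped, " footprint record(s) dropped (unknown transcript ",
            "or out of transcript bounds)")
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Duplicate members within a set are de-duplicated;
#' duplicate set names or empty sets are errors.
#'
#' @param path file path.
#' @return list of class `gene_set_collection`: `sets` (named list of
#'   character vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop_("GMT set with zero members at line ", short[1])
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop_("duplicate gene-set name: ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- stats::setNames(vapply(fields, `[[`, "", 2), nm)
  structure(list(sets = sets, description = desc),
            class = "gene_set_collection")
}

#' Read a FASTQ file (Phred+33)
#'
#' Strict 4-line-record FASTQ reader. The quality line is read by position
#' (a leading `@` in qualities is handled correctly). Sequence/quality
#' length mismatch or a truncated record is an error naming the record
#' index.
#'
#' @param path file path (may be gzipped).
#' @return `data.frame` with `read_id`, `sequence`, `quality` (raw Phred+33
#'   string). Use [phred_scores()] for numeric scores.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop_("truncated FASTQ record at record ", length(lines) %/% 4 + 1L)
  if (!length(lines))
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  idx <- seq(1, length(lines), by = 4)
  ids <- lines[idx]
  bad_hdr <- which(!startsWith(ids, "@"))
  if (length(bad_hdr)) stop_("malformed FASTQ header at record ", bad_hdr[1])
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  mism <- which(nchar(seqs) != nchar(quals) | nchar(seqs) == 0)
  if (length(mism))
    stop_("sequence/quality length mismatch at record ", mism[1])
  data.frame(read_id = sub("^@", "", ids), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Decode a Phred+33 quality string
#' @param quality character vector of quality strings.
#' @return list of integer Phred score vectors.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), floating values rendered with 6
#' significant digits so that a read-back round-trip agrees to rendering
#' precision.
#'
#' @param rows a `data.frame`.
#' @param path output path.
#' @param format only `"tsv"`.
#' @export
write_table <- function(rows, path, format = c("tsv")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  num <- vapply(rows, is.double, TRUE)
  rows[num] <- lapply(rows[num], signif, digits = 6)
  ok <- tryCatch({
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_("cannot write table to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path file path.
#' @return `data.frame`.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop_("table not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}
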