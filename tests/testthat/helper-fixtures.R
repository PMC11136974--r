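# Small in-code fixtures shared across test files.

# A handful of transcripts with known UTR5/CDS/UTR3 extents.
toy_annotation <- function() {
  riboquad:::validate_annotation(data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    transcript_id = c("t1", "t2a", "t2b", "t3"),
    total_length = c(900L, 600L, 450L, 300L),
    cds_start = c(100L, 50L, 30L, 60L),
    cds_end = c(700L, 500L, 330L, 240L),
    stringsAsFactors = FALSE))
}

toy_footprints <- function(transcript_id, start, length, assay = "RFP") {
  data.frame(transcript_id = transcript_id, start = as.integer(start),
             length = as.integer(length), assay = assay,
             stringsAsFactors = FALSE)
}

write_tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# FASTQ text for given sequences; qualities all at the given Phred score
# unless a quality string is supplied.
fastq_text <- function(seqs, quals = NULL, phred = 30) {
  if (is.null(quals))
    quals <- vapply(nchar(seqs),
                    function(n) strrep(intToUtf8(phred + 33), n), "")
  as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+", quals))
}

# Null two-group NB counts at a given dispersion (no planted effects).
null_simulation <- function(n_genes = 2000, phi = 0.05, seed = 1) {
  simulate_counts(sim_design(
    n_genes = n_genes, dispersion = phi,
    effect_props = c(null = 1, txn_only = 0, trans_only = 0, concordant = 0),
    seed = seed))
}

# Directory checksums ignoring the timestamped log.
dir_checksums <- function(dir) {
  files <- setdiff(list.files(dir), "run.log")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  sums
}
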