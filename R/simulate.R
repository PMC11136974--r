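#' Simulation design for a two-group, two-assay count experiment
#'
#' Describes a 3-vs-3 (by default) negative-binomial count experiment with
#' matched RNA and ribosome-footprint (RFP) assays and planted per-gene
#' effect classes:
#' \describe{
#'   \item{null}{no change in either assay.}
#'   \item{txn_only}{purely transcriptional regulation: RNA and RFP share
#'     the same log2 fold change, TE shift 0.}
#'   \item{trans_only}{purely translational regulation: RNA unchanged, RFP
#'     (and hence TE) shifted — the class the nine-quadrant B/H set should
#'     recover.}
#'   \item{concordant}{reinforcing regulation: RNA shifted and TE shifted
#'     by the same amount (RFP moves twice as far).}
#' }
#' Effect signs are assigned up/down with probability 1/2 per affected
#' gene.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per group (study design: 3).
#' @param lib_size_rna,lib_size_rfp expected total counts per library.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param effect_props named proportions for classes
#'   `null`, `txn_only`, `trans_only`, `concordant`; must sum to 1.
#' @param effect_log2 absolute planted log2 effect size.
#' @param te_base_log2 global baseline log2 TE offset applied to RFP means.
#' @param seed RNG seed.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(n_genes = 2000, n_per_group = 3,
                       lib_size_rna = 2e6, lib_size_rfp = 2e6,
                       dispersion = 0.05,
                       effect_props = c(null = 0.7, txn_only = 0.1,
                                        trans_only = 0.1, concordant = 0.1),
                       effect_log2 = 2, te_base_log2 = 0, seed = 1) {
  classes <- c("null", "txn_only", "trans_only", "concordant")
  if (!setequal(names(effect_props), classes))
    stop_("effect_props must be named ", paste(classes, collapse = ", "))
  effect_props <- effect_props[classes]
  if (abs(sum(effect_props) - 1) > 1e-8) stop_("effect proportions must sum to 1")
  if (dispersion < 0) stop_("dispersion must be >= 0")
  if (lib_size_rna <= 0 || lib_size_rfp <= 0) stop_("library sizes must be positive")
  if (n_per_group < 1) stop_("n_per_group must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 lib_size_rna = lib_size_rna, lib_size_rfp = lib_size_rfp,
                 dispersion = dispersion, effect_props = effect_props,
                 effect_log2 = effect_log2, te_base_log2 = te_base_log2,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate a transcript annotation
#'
#' One transcript per gene; UTR and CDS lengths drawn from log-normal
#' distributions around the given means, CDS lengths rounded up to a
#' multiple of 3 (minimum 30 nt). Deterministic given `seed`.
#'
#' @param n_genes number of genes.
#' @param utr5_mean,cds_mean,utr3_mean mean region lengths (nt); CDS mean
#'   must be at least 30.
#' @param seed RNG seed.
#' @return `transcript_annotation` data frame.
#' @export
make_annotation <- function(n_genes, utr5_mean = 100, cds_mean = 1200,
                            utr3_mean = 300, seed = 1) {
  if (cds_mean < 30) stop_("mean CDS length must be >= 30")
  if (n_genes == 0) return(validate_annotation(empty_annotation()))
  with_seed(seed, {
    # log-normal with modest spread; meanlog chosen so E[length] = mean
    draw <- function(mean, n, sdlog = 0.35)
      stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
    utr5 <- pmax(0L, as.integer(round(draw(utr5_mean, n_genes))))
    cds <- as.integer(round(draw(cds_mean, n_genes)))
    cds <- pmax(30L, cds + (3L - cds %% 3L) %% 3L)
    utr3 <- pmax(0L, as.integer(round(draw(utr3_mean, n_genes))))
    w <- floor(log10(n_genes)) + 1L
    ids <- formatC(seq_len(n_genes), width = w, flag = "0")
    validate_annotation(data.frame(
      gene_id = paste0("g", ids), transcript_id = paste0("t", ids),
      total_length = utr5 + cds + utr3,
      cds_start = utr5, cds_end = utr5 + cds,
      stringsAsFactors = FALSE))
  })
}

# Deterministically split n genes into the four classes by proportion.
assign_classes <- function(n, props) {
  counts <- diff(round(cumsum(c(0, props)) * n))
  counts[1] <- counts[1] + (n - sum(counts))  # absorb rounding in `null`
  rep(names(props), times = counts)
}

#' Simulate paired RNA and RFP count matrices with planted effects
#'
#' Baseline gene abundances are log-normal (`meanlog = 1.5`,
#' `sdlog = 1.5`), renormalized to relative weights. For gene g the group-1
#' RNA mean is `weight * lib_size_rna`; in group 2 it is scaled by
#' `2^(rna log2FC)`. The RFP mean is the RNA mean times
#' `(lib_size_rfp / lib_size_rna) * 2^(te_base_log2 + te shift)` with the
#' TE shift applied in group 2 only. Counts are NB with dispersion phi
#' (Poisson when phi = 0).
#'
#' @param design a [sim_design()].
#' @return list with `rna`, `rfp` (gene x sample integer matrices),
#'   `groups` (factor NC/HC), `truth` (`data.frame`: `gene_id`, `class`,
#'   `rna_log2fc`, `rfp_log2fc`, `te_log2fc`).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_genes
  npg <- design$n_per_group
  with_seed(design$seed, {
    w <- stats::rlnorm(n, meanlog = 1.5, sdlog = 1.5)
    w <- w / sum(w)
    cls <- sample(assign_classes(n, design$effect_props))
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    eff <- design$effect_log2 * sgn
    rna_fc <- ifelse(cls %in% c("txn_only", "concordant"), eff, 0)
    te_fc <- ifelse(cls == "trans_only", eff,
                    ifelse(cls == "concordant", eff, 0))
    rfp_fc <- rna_fc + te_fc

    rna_mu1 <- w * design$lib_size_rna
    rna_mu2 <- rna_mu1 * 2^rna_fc
    rfp_scale <- (design$lib_size_rfp / design$lib_size_rna) * 2^design$te_base_log2
    rfp_mu1 <- rna_mu1 * rfp_scale
    rfp_mu2 <- rna_mu2 * rfp_scale * 2^te_fc

    rcounts <- function(mu) {
      if (design$dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), size = 1 / design$dispersion, mu = mu)
    }
    draw_mat <- function(mu1, mu2) {
      m <- vapply(seq_len(2 * npg), function(j) {
        as.numeric(rcounts(if (j <= npg) mu1 else mu2))
      }, numeric(n))
      storage.mode(m) <- "integer"
      dimnames(m) <- list(truth_ids(n),
                          c(paste0("NC_", seq_len(npg)), paste0("HC_", seq_len(npg))))
      m
    }
    rna <- draw_mat(rna_mu1, rna_mu2)
    rfp <- draw_mat(rfp_mu1, rfp_mu2)
    truth <- data.frame(gene_id = rownames(rna), class = cls,
                        rna_log2fc = rna_fc, rfp_log2fc = rfp_fc,
                        te_log2fc = te_fc, stringsAsFactors = FALSE)
    list(rna = rna, rfp = rfp,
         groups = factor(rep(c("NC", "HC"), each = npg), levels = c("NC", "HC")),
         truth = truth)
  })
}

truth_ids <- function(n) {
  w <- floor(log10(max(n, 1))) + 1L
  paste0("g", formatC(seq_len(n), width = w, flag = "0"))
}

#' Footprint simulation parameters
#'
#' @param length_probs named probability vector over read lengths (nt);
#'   the default places ~78% of the mass on 27-32 nt within a 15-35 nt
#'   support, matching the expected footprint length profile.
#' @param frame_fidelity probability that a CDS P-site falls in frame 0.
#' @param region_probs named probabilities for `UTR5`, `CDS`, `UTR3`
#'   P-site placement (default 0.15/0.70/0.15).
#' @param reads_total number of footprints to draw.
#' @param psite_offset fixed P-site offset from the 5' read end (nt).
#' @param seed RNG seed.
#' @return list of class `footprint_sim_params`.
#' @export
footprint_sim_params <- function(length_probs = default_length_probs(),
                                 frame_fidelity = 0.9,
                                 region_probs = c(UTR5 = 0.15, CDS = 0.7, UTR3 = 0.15),
                                 reads_total = 50000, psite_offset = 12,
                                 seed = 1) {
  if (abs(sum(length_probs) - 1) > 1e-8) stop_("length_probs must sum to 1")
  if (is.null(names(length_probs))) stop_("length_probs must be named by length")
  if (!setequal(names(region_probs), c("UTR5", "CDS", "UTR3")) ||
      abs(sum(region_probs) - 1) > 1e-8)
    stop_("region_probs must be named UTR5/CDS/UTR3 and sum to 1")
  if (frame_fidelity < 0 || frame_fidelity > 1)
    stop_("frame_fidelity must be in [0, 1]")
  structure(list(length_probs = length_probs, frame_fidelity = frame_fidelity,
                 region_probs = region_probs[c("UTR5", "CDS", "UTR3")],
                 reads_total = as.integer(reads_total),
                 psite_offset = as.integer(psite_offset),
                 seed = as.integer(seed)),
            class = "footprint_sim_params")
}

#' @rdname footprint_sim_params
#' @export
default_length_probs <- function() {
  len <- 15:35
  p <- rep(0.22 / 15, length(len))
  p[len %in% 27:32] <- 0.78 / 6
  stats::setNames(p / sum(p), len)
}

# Sample, for each row, a position p uniform over {p in [lo, hi) :
# (p - anchor) %% 3 == frame}; frame = NA means no frame constraint.
# Returns NA where the set is empty.
sample_position <- function(lo, hi, anchor, frame) {
  n <- length(lo)
  out <- rep(NA_integer_, n)
  free <- is.na(frame)
  ok <- free & hi > lo
  out[ok] <- lo[ok] + as.integer(floor(stats::runif(sum(ok)) * (hi[ok] - lo[ok])))
  con <- which(!free)
  if (length(con)) {
    first <- lo[con] + (anchor[con] + frame[con] - lo[con]) %% 3L
    cnt <- pmax(0L, as.integer(ceiling((hi[con] - first) / 3)))
    has <- cnt > 0
    out[con[has]] <- first[has] +
      3L * as.integer(floor(stats::runif(sum(has)) * cnt[has]))
  }
  out
}

#' Simulate ribosome footprints with controlled length / region / frame
#'
#' Each read draws a gene (proportional to `abundance`), a region
#' (`region_probs`), and a length (`length_probs`). The P-site is placed
#' uniformly over the valid positions of that region — those for which the
#' read (start = P-site minus `psite_offset`) fits inside the transcript —
#' and, within the CDS, lands in frame 0 with probability
#' `frame_fidelity`, else uniformly in frames 1-2. Frame placement uses
#' only frame-clean transcripts (`frame_ok`). Draws with no valid
#' placement are redrawn; genes too short for any placement are skipped
#' with a warning.
#'
#' @param annotation `transcript_annotation`.
#' @param abundance named non-negative weights per gene (not all zero).
#' @param params a [footprint_sim_params()].
#' @param assay assay label stored on the records.
#' @return footprint `data.frame` (`transcript_id`, `start`, `length`,
#'   `assay`).
#' @export
simulate_footprints <- function(annotation, abundance, params,
                                assay = c("RFP", "RNA")) {
  assay <- match.arg(assay)
  stopifnot(inherits(params, "footprint_sim_params"))
  ab <- abundance[match(annotation$gene_id, names(abundance))]
  ab[is.na(ab)] <- 0
  if (any(ab < 0) || sum(ab) <= 0) stop_("abundance weights must be non-negative, not all zero")
  n_tx <- nrow(annotation)
  off <- params$psite_offset
  lens <- as.integer(names(params$length_probs))

  with_seed(params$seed, {
    n <- params$reads_total
    tx <- integer(n); ps <- rep(NA_integer_, n); ln <- integer(n)
    todo <- seq_len(n)
    for (round in 1:50) {
      m <- length(todo)
      if (!m) break
      g <- sample.int(n_tx, m, replace = TRUE, prob = ab)
      reg <- sample(c("UTR5", "CDS", "UTR3"), m, replace = TRUE,
                    prob = params$region_probs)
      l <- lens[sample.int(length(lens), m, replace = TRUE,
                           prob = params$length_probs)]
      L <- annotation$total_length[g]
      cs <- annotation$cds_start[g]; ce <- annotation$cds_end[g]
      reg_lo <- ifelse(reg == "UTR5", 0L, ifelse(reg == "CDS", cs, ce))
      reg_hi <- ifelse(reg == "UTR5", cs, ifelse(reg == "CDS", ce, L))
      lo <- pmax(reg_lo, off)                 # start >= 0
      hi <- pmin(reg_hi, L - l + off)         # start + length <= L
      frame <- rep(NA_integer_, m)
      in_cds <- reg == "CDS" & annotation$frame_ok[g]
      if (any(in_cds)) {
        u <- stats::runif(sum(in_cds))
        frame[in_cds] <- ifelse(u < params$frame_fidelity, 0L,
                                ifelse(stats::runif(sum(in_cds)) < 0.5, 1L, 2L))
      }
      p <- sample_position(lo, hi, cs, frame)
      ok <- !is.na(p)
      tx[todo[ok]] <- g[ok]; ps[todo[ok]] <- p[ok]; ln[todo[ok]] <- l[ok]
      todo <- todo[!ok]
    }
    if (length(todo)) {
      warn_(length(todo), " footprint draw(s) had no valid placement and were dropped")
      keep <- !is.na(ps)
      tx <- tx[keep]; ps <- ps[keep]; ln <- ln[keep]
    }
    data.frame(transcript_id = annotation$transcript_id[tx],
               start = ps - off, length = ln, assay = assay,
               stringsAsFactors = FALSE)
  })
}

#' Write the simulation truth table
#' @param truth the `truth` element of [simulate_counts()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) write_table(truth, path)
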