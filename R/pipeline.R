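#' Build a pipeline configuration
#'
#' Collects every tunable of the simulate -> qc -> quantify -> de ->
#' integrate -> enrich chain in one validated list. Any entry can be
#' overridden via `...`; `yaml_path` loads overrides from a YAML file
#' first (explicit `...` arguments win).
#'
#' @param yaml_path optional YAML file of overrides.
#' @param ... named overrides of the defaults listed below.
#' @return list of class `pipeline_config`. Defaults: 2000 genes, 3 vs 3,
#'   library sizes 2e6, dispersion 0.05, |log2 effect| 2, 100000
#'   footprints, P-site offset 12, quality threshold Q20, lfc_min 1,
#'   alpha 0.05, min_rpkm 0.1, min_count 1, seed 1.
#' @export
pipeline_config <- function(yaml_path = NULL, ...) {
  cfg <- list(
    # simulation design (used when no count paths are given)
    simulate = TRUE,
    n_genes = 2000, n_per_group = 3,
    lib_size_rna = 2e6, lib_size_rfp = 2e6,
    dispersion = 0.05,
    effect_props = c(null = 0.7, txn_only = 0.1, trans_only = 0.1,
                     concordant = 0.1),
    effect_log2 = 2, te_base_log2 = 0,
    reads_total = 100000, frame_fidelity = 0.9,
    region_probs = c(UTR5 = 0.15, CDS = 0.7, UTR3 = 0.15),
    # input paths (alternative to simulation)
    annotation_path = NULL, footprints_path = NULL,
    counts_rna_path = NULL, counts_rfp_path = NULL,
    groups = NULL, gmt_path = NULL,
    # thresholds
    lfc_min = 1, alpha = 0.05, min_rpkm = 0.1, min_count = 1,
    default_offset = 12, quality_threshold = 20,
    gsea_permutations = 200,
    seed = 1
  )
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) stop_("config file not found: ", yaml_path)
    over <- yaml::read_yaml(yaml_path)
    for (nm in names(over)) {
      v <- over[[nm]]
      if (nm %in% c("effect_props", "region_probs")) {
        # YAML parses an unquoted `null:` mapping key as the empty name
        v <- unlist(v)
        names(v)[!nzchar(names(v))] <- "null"
      }
      cfg[[nm]] <- v
    }
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_("unknown config entr", if (length(unknown) > 1) "ies: " else "y: ",
          paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$lfc_min >= 0,
            cfg$min_rpkm >= 0, cfg$min_count >= 0)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(logfile, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

read_counts_tsv <- function(path) {
  df <- read_table_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

counts_to_df <- function(m) {
  cbind(data.frame(gene_id = rownames(m), stringsAsFactors = FALSE),
        as.data.frame(m))
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> qc -> quantify -> de -> integrate -> enrich
#' with one config, writing every stage result as TSV under `outdir`.
#' Randomness is fanned out from the global seed by a fixed per-stage
#' derivation (seed + stage index), so identical config + seed gives
#' byte-identical outputs and each stage is individually reproducible. A
#' stage failure aborts with the failing stage named and leaves a
#' `FAILED_<stage>` marker file next to the partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) list of class `run_report`: `stages` (data frame of
#'   per-stage input/output row counts) and `headline` (DEG counts per
#'   assay, TE-DE counts, quadrant census, translation-only set size).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  stages <- list()
  current_stage <- "setup"
  record <- function(stage, n_in, n_out, note = "") {
    stages[[stage]] <<- data.frame(stage = stage, n_in = n_in, n_out = n_out,
                                   note = note, stringsAsFactors = FALSE)
  }
  on_fail <- function(e) {
    file.create(file.path(outdir, paste0("FAILED_", current_stage)))
    stop_("pipeline stage '", current_stage, "' failed: ", conditionMessage(e))
  }

  tryCatch({
    ## stage 1: simulate (or load supplied inputs)
    current_stage <- "simulate"
    seed1 <- config$seed + 1L
    if (isTRUE(config$simulate) && is.null(config$counts_rna_path)) {
      stage_log(logfile, "simulate", paste0(config$n_genes, " genes, ",
                config$n_per_group, " vs ", config$n_per_group))
      design <- sim_design(n_genes = config$n_genes,
                           n_per_group = config$n_per_group,
                           lib_size_rna = config$lib_size_rna,
                           lib_size_rfp = config$lib_size_rfp,
                           dispersion = config$dispersion,
                           effect_props = config$effect_props,
                           effect_log2 = config$effect_log2,
                           te_base_log2 = config$te_base_log2,
                           seed = seed1)
      ann <- make_annotation(config$n_genes, seed = seed1)
      sim <- simulate_counts(design)
      rna_counts <- sim$rna; rfp_counts <- sim$rfp; groups <- sim$groups
      fp_params <- footprint_sim_params(frame_fidelity = config$frame_fidelity,
                                        region_probs = config$region_probs,
                                        reads_total = config$reads_total,
                                        psite_offset = config$default_offset,
                                        seed = seed1)
      abundance <- stats::setNames(rowMeans(rfp_counts) + 1e-9, rownames(rfp_counts))
      fp <- simulate_footprints(ann, abundance, fp_params)
      write_table(ann[, c("gene_id", "transcript_id", "total_length",
                          "cds_start", "cds_end")],
                  file.path(outdir, "annotation.tsv"))
      write_table(fp, file.path(outdir, "footprints.tsv"))
      write_table(counts_to_df(rna_counts), file.path(outdir, "counts_rna.tsv"))
      write_table(counts_to_df(rfp_counts), file.path(outdir, "counts_rfp.tsv"))
      write_truth(sim$truth, file.path(outdir, "truth.tsv"))
      record("simulate", config$n_genes, nrow(fp))
    } else {
      stage_log(logfile, "simulate", "disabled; loading supplied inputs")
      ann <- read_annotation(config$annotation_path)
      rna_counts <- read_counts_tsv(config$counts_rna_path)
      rfp_counts <- read_counts_tsv(config$counts_rfp_path)
      if (is.null(config$groups)) stop_("config$groups required with supplied counts")
      groups <- factor(config$groups, levels = unique(config$groups))
      fp <- if (!is.null(config$footprints_path))
        read_footprints(config$footprints_path, ann) else NULL
      record("simulate", 0L, nrow(rna_counts), "loaded inputs")
    }
    if (any(table(groups) < 2)) stop_("need >= 2 samples per group")

    ## stage 2: footprint qc
    current_stage <- "qc"
    if (!is.null(fp)) {
      stage_log(logfile, "qc", paste0(nrow(fp), " footprint records"))
      n_in <- nrow(fp)
      fp_kept <- length_filter(fp)
      lh <- length_histogram(fp_kept)
      write_table(data.frame(length = as.integer(names(lh$counts)),
                             count = as.integer(lh$counts)),
                  file.path(outdir, "qc_length_histogram.tsv"))
      occ <- region_occupancy(fp_kept, ann, default_offset = config$default_offset)
      write_table(data.frame(region = names(occ$fractions),
                             fraction = as.numeric(occ$fractions)),
                  file.path(outdir, "qc_region_occupancy.tsv"))
      for (anchor in c("start_codon", "stop_codon")) {
        mp <- metagene_profile(fp_kept, ann, anchor,
                               default_offset = config$default_offset)
        write_table(data.frame(offset = as.integer(names(mp$counts)),
                               count = as.integer(mp$counts)),
                    file.path(outdir, paste0("qc_metagene_", anchor, ".tsv")))
      }
      per <- periodicity(fp_kept, ann, default_offset = config$default_offset)
      write_table(data.frame(frame = 0:2,
                             fraction = as.numeric(per$frame_fractions)),
                  file.path(outdir, "qc_periodicity.tsv"))
      record("qc", n_in, nrow(fp_kept),
             paste0("modal_length=", lh$modal_length))
    } else {
      record("qc", 0L, 0L, "no footprints supplied; skipped")
    }

    ## stage 3: quantify (RPKM; CDS lengths for RFP, transcript for RNA)
    current_stage <- "quantify"
    stage_log(logfile, "quantify", "RPKM normalization")
    len_rna <- gene_lengths(ann, "full_transcript")
    len_rfp <- gene_lengths(ann, "cds")
    rna_rpkm <- rpkm(rna_counts, len_rna[rownames(rna_counts)])
    rfp_rpkm <- rpkm(rfp_counts, len_rfp[rownames(rfp_counts)])
    write_table(counts_to_df(round(rna_rpkm, 6)), file.path(outdir, "rpkm_rna.tsv"))
    write_table(counts_to_df(round(rfp_rpkm, 6)), file.path(outdir, "rpkm_rfp.tsv"))
    venn <- lapply(levels(groups), function(g)
      detected_overlap(rna_counts, rfp_counts, groups, g, config$min_count))
    write_table(data.frame(group = levels(groups),
                           do.call(rbind, venn)),
                file.path(outdir, "detected_overlap.tsv"))
    record("quantify", nrow(rna_counts), nrow(rna_rpkm))

    ## stage 4: differential expression per assay
    current_stage <- "de"
    stage_log(logfile, "de", "NB exact tests")
    de_rna <- differential_expression(rna_counts, groups, rna_rpkm,
                                      lfc_min = config$lfc_min,
                                      alpha = config$alpha)
    de_rfp <- differential_expression(rfp_counts, groups, rfp_rpkm,
                                      lfc_min = config$lfc_min,
                                      alpha = config$alpha)
    write_table(de_rna, file.path(outdir, "de_rna.tsv"))
    write_table(de_rfp, file.path(outdir, "de_rfp.tsv"))
    record("de", nrow(rna_counts),
           sum(de_rna$call != "ns") + sum(de_rfp$call != "ns"),
           paste0("phi_rna=", signif(attr(de_rna, "dispersion")$phi, 3),
                  ",phi_rfp=", signif(attr(de_rfp, "dispersion")$phi, 3)))

    ## stage 5: translatome integration
    current_stage <- "integrate"
    stage_log(logfile, "integrate", "TE + nine-quadrant classification")
    te <- compute_te(rna_rpkm, rfp_rpkm, groups, config$min_rpkm)
    dte <- diff_te(te, lfc_min = config$lfc_min, alpha = config$alpha)
    quad <- quadrant_classify(de_rna, de_rfp)
    tonly <- translation_only_set(quad)
    write_table(data.frame(gene_id = rownames(te$log2_te),
                           te$group_mean_log2_te),
                file.path(outdir, "te_group_means.tsv"))
    write_table(dte, file.path(outdir, "diff_te.tsv"))
    write_table(quad, file.path(outdir, "quadrants.tsv"))
    writeLines(tonly, file.path(outdir, "translation_only.txt"))
    lv <- levels(groups)
    fitv <- fit_regression(te$group_mean_log2_te[, lv[1]],
                           te$group_mean_log2_te[, lv[2]])
    write_table(data.frame(slope = fitv$slope, intercept = fitv$intercept,
                           r_squared = fitv$r_squared, n = fitv$n),
                file.path(outdir, "te_regression.tsv"))
    lg_rfp <- log2(rfp_rpkm[te$eligible, , drop = FALSE] + config$min_rpkm)
    fin <- function(x) x[is.finite(x)]
    mw_rows <- list(
      rfp_abundance = mann_whitney(fin(rowMeans(lg_rfp[, groups == lv[1], drop = FALSE])),
                                   fin(rowMeans(lg_rfp[, groups == lv[2], drop = FALSE]))),
      te = mann_whitney(fin(te$group_mean_log2_te[, lv[1]]),
                        fin(te$group_mean_log2_te[, lv[2]])))
    write_table(data.frame(measure = names(mw_rows),
                           U = vapply(mw_rows, `[[`, 0, "U"),
                           pvalue = vapply(mw_rows, `[[`, 0, "pvalue"),
                           method = vapply(mw_rows, `[[`, "", "method")),
                file.path(outdir, "rank_tests.tsv"))
    for (g in lv)
      write_table(ecdf_table(fin(te$group_mean_log2_te[, g])),
                  file.path(outdir, paste0("ecdf_te_", g, ".tsv")))
    census <- table(factor(quad$quadrant, levels = LETTERS[1:9]))
    record("integrate", nrow(quad), length(tonly),
           paste0("census=", paste(census, collapse = "/")))

    ## stage 6: enrichment (needs a GMT collection)
    current_stage <- "enrich"
    if (!is.null(config$gmt_path)) {
      if (!file.exists(config$gmt_path))
        stop_("GMT file not found: ", config$gmt_path)
      stage_log(logfile, "enrich", config$gmt_path)
      gmt <- read_gmt(config$gmt_path)
      ora_res <- ora(tonly, quad$gene_id, gmt)
      write_table(ora_res, file.path(outdir, "ora_translation_only.tsv"))
      ranked <- rank_genes(rfp_rpkm, groups)
      gsea_res <- gsea(ranked, gmt, n_perm = config$gsea_permutations,
                       seed = config$seed + 6L)
      write_table(gsea_res, file.path(outdir, "gsea_rfp.tsv"))
      record("enrich", length(gmt$sets), nrow(ora_res))
    } else {
      record("enrich", 0L, 0L, "no GMT supplied; skipped")
    }
  }, error = on_fail)

  stages_df <- do.call(rbind, stages)
  rownames(stages_df) <- NULL
  headline <- list(
    n_deg_rna = sum(de_rna$call != "ns"),
    n_deg_rna_up = sum(de_rna$call == "up"),
    n_deg_rna_down = sum(de_rna$call == "down"),
    n_deg_rfp = sum(de_rfp$call != "ns"),
    n_deg_rfp_up = sum(de_rfp$call == "up"),
    n_deg_rfp_down = sum(de_rfp$call == "down"),
    n_te_up = sum(dte$call == "up"),
    n_te_down = sum(dte$call == "down"),
    quadrant_census = stats::setNames(as.integer(census), names(census)),
    n_translation_only = length(tonly))
  write_table(stages_df, file.path(outdir, "report.tsv"))
  writeLines(c(
    "riboquad run summary",
    sprintf("seed: %d", config$seed),
    sprintf("transcriptional DEGs: %d (%d up / %d down)",
            headline$n_deg_rna, headline$n_deg_rna_up, headline$n_deg_rna_down),
    sprintf("translational DEGs: %d (%d up / %d down)",
            headline$n_deg_rfp, headline$n_deg_rfp_up, headline$n_deg_rfp_down),
    sprintf("TE DEGs: %d up / %d down", headline$n_te_up, headline$n_te_down),
    sprintf("quadrant census (A..I): %s",
            paste(headline$quadrant_census, collapse = " ")),
    sprintf("translation-only genes (B+H): %d", headline$n_translation_only)),
    file.path(outdir, "summary.txt"))
  stage_log(logfile, "done", outdir)
  invisible(structure(list(stages = stages_df, headline = headline),
                      class = "run_report"))
}
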