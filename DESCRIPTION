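Package: riboquad
Title: Ribo-Seq and RNA-Seq Integration for Translatome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for integrating ribosome profiling (Ribo-seq)
    with matched RNA-seq to find genes regulated at the translational but not
    the transcriptional level. Provides footprint quality control (read
    filtering, length distribution, CDS/UTR occupancy, metagene profiles,
    three-nucleotide periodicity), gene-level counting and RPKM
    normalization, a negative-binomial conditional exact test with common
    dispersion for two-group differential expression, translation-efficiency
    (TE) computation with differential TE, nine-quadrant
    transcriptome-translatome classification, over-representation analysis
    and a gene-set enrichment (GSEA) engine, plus a synthetic-data generator
    with planted transcription-only, translation-only and concordant effects
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    edgeR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
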