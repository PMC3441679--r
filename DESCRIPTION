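Package: xachrom
Title: Chromosome-Scale Chromatin Signal Analysis for X:Autosome Enrichment
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying chromosome-wide enrichment of chromatin
    marks, built around the C. elegans dosage compensation setting in which
    H4K20me1 is enriched across the hermaphrodite X chromosome. Implements
    standardization of log2 ChIP/Input ratio tracks to z-scores against an
    autosomal reference, replicate averaging, sliding median smoothing,
    per-chromosome signal summaries and an X:autosome enrichment statistic;
    anchored meta-gene profiles at TSS/TES stratified by expression quantile
    and chromosome class; detection and center-anchored profiling of long
    annotation-free intergenic regions; a fusion-chromosome coordinate model
    with an ectopic-spreading score; expression normalization, probe
    summarization and signal-expression correlation; delta-delta-Ct qPCR
    relative quantification; and a synthetic data generator with known ground
    truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, ChIPchip, Epigenetics, Coverage, GeneExpression,
    Normalization, Software
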