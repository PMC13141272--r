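Package: k4gauge
Title: Spike-In Normalised H3K4 Methylation ChIP-Seq and Transcriptome
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of spike-in normalised histone H3 lysine 4
    (H3K4) methylation ChIP-seq together with matched RNA-seq, as used to
    dissect the roles of the SET/MLL scaffolding subunits WDR-5 and RBBP-5
    in C. elegans embryos. Provides spike-in scaling-factor derivation and
    downsampling normalisation of binned coverage, mark-specific broadPeak
    post-filtering and mutually exclusive regulatory classification,
    TSS/enhancer signal metaprofiles with k-means High/Low clustering,
    chromosome-level coverage uniformity statistics, differential-expression
    post-processing (net transcriptome change percent, baseline-stratified
    rank tests, chromosome enrichment, overlap and restoration set logic,
    Cook's distance sensitivity), relative qPCR quantification by the
    delta-delta-Ct method, and a seeded synthetic-data generator so that
    every stage runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
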