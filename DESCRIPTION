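Package: chromdiff
Title: Differential Chromatin and Regulatory Variant Analysis for Tissue ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a bespoke ChIP-seq analysis workflow
    for comparing histone-modification and transcription-factor enrichment
    between diseased and normal tissue samples. Provides a fragment-extension
    pileup peak caller with summit detection and E-box motif annotation,
    differential enrichment ranking of unioned peak regions with nearest-TSS
    gene assignment, TSS footprint profiling with joint normalization,
    genomic-distribution classification, a multi-stage regulatory SNP
    filtering and annotation cascade (quality/depth filters, known/novel
    split against versioned variant catalogues, GWAS keyword overlap and LD
    proxy expansion, peak-overlap categorization), and the qPCR enrichment
    call statistic. A synthetic-data generator with a recorded truth table
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
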