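Package: natedit
Title: Differential A-to-I RNA Editing Analysis with Natural Antisense
    Transcript Prioritization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for cohort-level analysis of A-to-I RNA editing calls
    from breast cancer RNA-seq studies. Implements the downstream
    site-filter chain (A-to-G/T-to-C strand consistency, Alu-overlap
    retention, SNP exclusion), depth-normalized per-sample editing burden
    with Mann-Whitney group comparison, and prioritization of candidate
    sites by prevalence-ratio Z-scores restricted to positions overlapped
    by natural antisense transcripts. Also provides qPCR relative
    quantification (2^-ddCt) and first-order RNA decay / half-life
    estimation for transcription-shutoff time courses, plus a synthetic
    cohort generator with planted differential sites for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Transcriptomics, GeneExpression, Sequencing, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
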