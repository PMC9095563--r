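Package: ptrOmics
Title: Integrative Nascent and Steady-State Transcriptomics for
    Post-Transcriptional Regulation and miRNA Master-Regulator Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to integrate nascent transcription (ChRO-seq/PRO-seq
    polymerase-position signal), steady-state RNA-seq and small RNA-seq in
    order to classify genes as transcriptionally versus post-transcriptionally
    regulated and to nominate candidate master miRNA regulators. Implements
    gene-body quantification with promoter pause-region exclusion, a
    negative-binomial Wald differential-expression core with median-of-ratios
    normalization and trend-shrunken dispersions, a two-factor
    (assay x condition) interaction test defining gain/loss of
    post-transcriptional suppression (GPS/LPS) gene sets, canonical miRNA
    seed-site detection (8mer, 7mer-m8, 7mer-A1) with cross-species
    conservation filtering, and a Monte-Carlo gene-list target-site density
    enrichment test. A synthetic-study generator with planted effects makes
    every stage verifiable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    optparse
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
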