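Package: brainchrom
Title: Chromatin Accessibility QTL and Heritability Analysis for Postmortem Brain ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of case-control chromatin accessibility
    studies: consensus peak construction and quantification, TMM
    normalization, shuffle-null enrichment QC, iterative principal-component
    covariate selection, negative-binomial differential accessibility with
    sex-chromosome-aware routing, cis chromatin-QTL mapping with
    beta-approximated permutation significance and Storey q-values, allelic
    imbalance validation, cQTL-eQTL sharing and Bayesian colocalization, and
    partitioned (stratified LD-score) heritability enrichment. Ships a
    synthetic-data generator with known ground truth so every stage is
    testable without access to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    MASS,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
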