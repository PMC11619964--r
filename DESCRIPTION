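Package: moals
Title: Multi-Omics Integration for ALS with Variational Autoencoder Embeddings and Multi-Task Survival Heads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the MOALS framework for multi-omics analysis of
    amyotrophic lateral sclerosis cohorts: fuzzy k-means clustering of gene
    expression profiles with local hypergeometric pathway enrichment for
    pathway-level gene selection, consequence-tier scoring of rare annotated
    variants aggregated into per-sample gene-burden features, and a
    variational autoencoder deep embedding with multi-task downstream heads
    (case/control classification, onset-age regression, and multi-task
    logistic regression survival) trained in three stages with
    GradNorm-balanced loss weighting. Includes a synthetic-cohort generator
    with planted latent structure, a stratified cross-validation harness with
    classification, regression and survival metrics (Harrell's C-index,
    IPCW integrated Brier score), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    tools,
    jsonlite,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
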