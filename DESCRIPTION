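Package: MeninGrade
Title: Transcriptomic Reclassification of WHO Grade 2 Meningiomas
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-study expression preprocessing (quantile normalization,
    gene-intersection merging, global standardization, empirical-Bayes batch
    correction), single-gene differential expression, weighted co-expression
    network modules with first-principal-component meta-genes, fuzzy C-means
    soft clustering optimized under a prevalence-balanced sigmoidal
    separation cost, and membership-threshold reclassification of WHO grade 2
    meningiomas into grade 1-like and grade 3-like subgroups, with
    recurrence-rate and module-concordance validation. Includes a synthetic
    multi-batch cohort generator with planted co-expression modules and
    latent grade 2 subgroups so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    sva,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, Clustering, Classification, BatchEffect,
    GeneExpression, Network
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'MeninGrade-package.R'
    'utils.R'
    'synth.R'
    'preprocess.R'
    'diffexpr.R'
    'coexpression.R'
    'reclassify.R'
    'validate.R'
    'io.R'
    'pipeline.R'
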