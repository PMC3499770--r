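Package: statisOmics
Title: STATIS and Dual-STATIS Compromise Analysis of Multi-Condition
    Time-Course Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Joint analysis of K gene-by-time expression tables collected
    under related experimental conditions. Implements the STATIS family of
    multi-table methods: per-table cross-product matrices, the RV
    congruence coefficient, eigenvector-derived table weights, the weighted
    compromise matrix and its mass-metric eigendecomposition, global and
    per-table factor scores, loadings, and row/column/table contributions,
    together with the dual (time-point) variant. Includes informative-gene
    filtering by fold-change and coefficient of variation, control-condition
    normalization, bootstrap-over-tables significance ratios,
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    correction, RV-based condition clustering with Newick export, and a
    synthetic multi-condition time-series generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'TableCollection-methods.R'
    'io.R'
    'preprocess.R'
    'statis.R'
    'bootstrap.R'
    'enrichment.R'
    'cluster.R'
    'simulate.R'
    'pipeline.R'
    'utils.R'
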