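Package: scmeta
Title: Cross-Dataset Meta-Analysis of Single-Cell RNA-Seq Immune Profiles
Version: 0.1.0
Authors@R:
    person("scmeta", "Developers", email = "scmeta@example.org", role = c("aut", "cre"))
Description: Tools for quantifying concordance between independently generated
    single-cell RNA-seq datasets and for building an integrated immune
    meta-atlas. Provides a ground-truth synthetic UMI count simulator,
    Matrix Market / CSV ingestion with barcode-level filtering, log
    normalization, PCA, graph clustering, a simplified mutual-nearest-neighbor
    integration, marker-panel subpopulation annotation, between-dataset
    concordance statistics (proportion chi-squared tests, housekeeping-gene
    noise, pseudobulk correlations, rank-rank hypergeometric overlap, top-k
    abundance agreement), Wilcoxon rank-sum differential expression with dual
    fold-change-ratio and Bonferroni gates, the difference-of-differences
    (DoD) interaction statistic that partitions between-dataset differential
    expression into uniform-shift versus subpopulation-specific components,
    and per-subpopulation meta-signature extraction against a reference
    compartment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
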