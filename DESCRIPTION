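Package: gbmnes
Title: Cell-Type Enrichment Landscape and Prognostic Stratification of
    Glioblastoma Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rank-based cell-type enrichment analysis of the glioblastoma
    microenvironment. Scores curated gene signatures in bulk expression
    cohorts with a Mann-Whitney normalized enrichment score (NES), screens
    signatures against overall survival with univariate Cox regression,
    stratifies cohorts into negative/positive immune response classes by
    hierarchical clustering of z-scored NES, identifies transformed cells in
    scRNA-seq data from moving-average chromosomal expression profiles
    (chromosome 7 gain / chromosome 10 loss), and assigns single-cell samples
    to the bulk-derived classes through a positive-Spearman fold-change rule.
    Includes a fully seeded synthetic-data generator with ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    methods,
    stats,
    survival,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
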