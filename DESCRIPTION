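Package: ipfsubsets
Title: Transcriptome-Based Stratification of Pulmonary Fibrosis Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers and characterises molecular subsets of idiopathic
    pulmonary fibrosis (IPF) patients from lung transcriptomes. Derives
    minimal cell-type marker signatures from annotated single-cell RNA-seq
    data by a greedy AUROC prefix search, projects them onto bulk cohorts
    with a gene set variation analysis (GSVA) enrichment score implemented
    from first principles, identifies patient subsets by consensus
    clustering with PAC-based model selection, and runs the downstream
    subset statistics: covariate-adjusted differential expression,
    cross-cohort log-fold-change replication, Kruskal-Wallis/Dunn
    comparisons of signature scores, permutation-based ligand-receptor
    inference, subset classifiers with recursive feature elimination, and
    drug-response signature scoring. Ships a synthetic-cohort generator
    with planted cell types and patient subsets so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    limma,
    withr
Config/testthat/edition: 3
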