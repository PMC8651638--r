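Package: endotypr
Title: Transcriptomic Endophenotype Discovery for Pulmonary Arterial
    Hypertension Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering and validating
    RNA-defined patient subgroups (endophenotypes) in whole-blood
    transcriptomes of idiopathic and heritable pulmonary arterial
    hypertension cohorts. Covers TPM matrix preprocessing (transcript
    aggregation, expression filtering, sex-chromosome gene removal,
    hyperbolic arcsine transformation), stability-selected spectral
    clustering with ensemble internal-index voting for the number of
    subgroups, L1-penalised gene signatures, clinical-feature signature
    search with transfer classification of independent cohorts,
    Kaplan-Meier / log-rank / Cox survival validation, gene-clinical
    Spearman correlation networks, and delta-delta-Ct qPCR confirmation.
    Includes a synthetic cohort generator emulating the statistical
    structure of such studies so every stage is testable without access
    to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    cluster,
    MASS,
    nnet,
    e1071,
    ranger,
    class,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
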