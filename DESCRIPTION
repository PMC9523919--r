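Package: crgi
Title: Drug Response-Related Genetic Interactions of Chromatin Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers chromatin-regulator synthetic-lethal (CSL) and
    synthetic-viable (CSV) gene pairs from multiple perturbation screens
    (CRISPR knockout and shRNA dependency scores), builds a multi-screen
    consensus with Fisher's combined probability test, promotes consensus
    pairs to drug-response biomarkers using pharmacogenomic IC50/AUC
    matrices and drug-target maps, and characterises the resulting
    gene-drug networks (permutation-null protein-protein interaction
    enrichment, drug-pair similarity via shared partners and ATC codes).
    Candidate interactions are validated on patient cohorts through
    co-expression/co-methylation, directional differential-feature tests,
    per-sample score shifts, pathway enrichment, and Kaplan-Meier /
    log-rank survival stratification by mutation-plus-expression rules.
    A seeded synthetic-data generator emulates every input so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
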