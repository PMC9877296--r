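Package: gsmir
Title: Knowledge-Group-Based miRNA Biomarker Discovery by Grouping, Scoring and Modeling
Version: 0.1.0
Authors@R:
    person("GSM", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a Grouping-Scoring-Modeling (G-S-M) pipeline for
    discovering disease-associated miRNA biomarkers from two-class miRNA
    expression profiles combined with prior miRNA-disease association
    knowledge. Disease groups of miRNAs are turned into two-class
    sub-datasets, scored by Monte-Carlo cross-validated random-forest
    classification accuracy, accumulated in rank order for cumulative model
    evaluation, and prioritized across resampling iterations with robust
    rank aggregation (order-statistic beta scores with Bonferroni
    correction). Includes a seeded synthetic-data generator with planted
    differentially expressed miRNAs and enriched groups so the whole
    pipeline is testable without access to repository-scale expression or
    association data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
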