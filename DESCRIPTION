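Package: concordia
Title: Cross-Cohort Directional Concordance of Cancer Omics Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether candidate oncogenes and tumor suppressor
    genes change in consistent directions across independent cancer-vs-normal
    cohorts. Implements a SAM-style permutation-FDR caller for differential
    expression, a beta-value based t-test caller for differential methylation,
    a simplified GISTIC-style G-score caller for copy-number alterations, an
    underflow-safe binomial test of directional consistency, candidate-gene
    direction-frequency statistics, and mutation-state-stratified expression
    testing. A seeded synthetic-data generator produces paired cohorts with
    planted effects and truth tables so the entire analysis runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
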