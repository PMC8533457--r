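Package: regnetmr
Title: Master Regulator Discovery from Mutual-Information Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transcription-factor-centric regulatory networks from
    expression data by mutual information with permutation-based edge
    significance and data-processing-inequality pruning, identifies master
    regulators of a disease signature by hypergeometric regulon enrichment,
    scores per-sample regulon activity with a two-tailed gene-set enrichment
    statistic, and applies a cross-cohort, cross-disease specificity filter to
    prioritise condition-specific master regulators. Includes microarray
    probe-to-gene collapsing by a geometric variability score, a synthetic-data
    generator that plants known regulons and disease drivers for end-to-end
    validation, and a reproducible multi-cohort pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
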