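Package: prolifsig
Title: Proliferation Expression Signatures from Growth-Annotated Cell Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every gene in an expression panel for its association with
    cellular proliferation, contrasting cancerous and non-cancerous panels.
    Computes per-gene proliferation indices (Spearman or regression-slope
    based) against growth-rate or doubling-time measurements, a differential
    index for genes positively associated with cancerous but negatively with
    non-cancerous proliferation, rank-based gene-set and bin enrichment
    statistics, penalized-regression growth-rate predictors with
    random-signature empirical nulls, and an expression-based survival
    stratification (predicted growth, two-means split, logrank). A bundled
    synthetic-data generator with a ground-truth ledger makes the full
    pipeline testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
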