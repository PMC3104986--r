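Package: npcps
Title: Non-Parametric Change-Point Detection of Differential Gene Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects differential gene expression confined to a subset of
    cancer samples by locating a change point in the ordered expression
    profile of each gene. The test statistic is a modified Kolmogorov
    distance between the empirical distribution of a candidate tail segment
    and a reference distribution estimated from the normal-group samples,
    evaluated on a fixed probability grid and maximised over candidate
    change-point positions. The package also implements seven comparison
    statistics for cancer-outlier detection (pooled t, COPA, OS, ORT, MOST,
    PPST and a likelihood-ratio scan), a synthetic expression-matrix
    generator with normal and skew-normal bases, and an evaluation harness
    producing miss-rate tables, change-point recovery tables, ROC/AUC grids
    and rank-correlation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
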