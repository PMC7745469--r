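Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection by p-value thresholding and
    greedy LD clumping, allele harmonization across study sources
    (including strand flips and palindromic variants resolved by allele
    frequency), instrument-strength diagnostics (variance explained and
    F-statistics), and five causal estimators (Wald ratio,
    inverse-variance-weighted, MR-Egger, weighted median, weighted mode)
    with Cochran's Q heterogeneity, leave-one-SNP-out series, scatter
    data, and analytic power. Supports multivariable MR with conditional
    F-statistics, and a two-step MR mediation workflow that screens a
    metabolite panel under Benjamini-Hochberg false-discovery-rate
    control, classifies direction consistency, and adjusts exposure
    effects for representative mediators. Includes a summary-statistics
    simulator with known ground truth (pleiotropy, LD blocks, mediator
    panels with class structure) so the whole pipeline is testable
    without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
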