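Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-phase two-sample Mendelian randomization (MR)
    mediation analysis of GWAS summary statistics: reading, validation and
    effect-allele harmonization of summary-statistics tables (including
    frequency-based palindromic-SNP resolution), instrument selection by
    p-value threshold, greedy LD clumping and F-statistic filtering,
    univariable MR estimators (Wald ratio, fixed/random-effects
    inverse-variance weighting, MR-Egger regression, weighted median with
    bootstrap standard errors), Cochran's Q heterogeneity testing, the
    MR-PRESSO global, outlier and distortion tests, replication
    meta-analysis, multivariable MR, and a two-step mediation decomposition
    reporting the proportion of an exposure's effect transmitted through a
    mediator.  A synthetic GWAS summary-statistics generator with known
    causal structure makes every pipeline stage testable without consortium
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    metafor,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
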