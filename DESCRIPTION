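Package: mrmediate
Title: Two-Sample, Multivariable and Two-Step Mediation Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection and LD clumping, allele
    harmonization with palindromic-variant removal, instrument-strength F
    statistics, the inverse-variance-weighted estimator with multiplicative
    random effects plus MR-Egger, weighted-median and mode-based estimators,
    sensitivity diagnostics (Cochran's Q, Egger intercept, MR-PRESSO outlier
    correction, leave-one-out), multivariable IVW, and two-step mediation
    analysis with delta-method standard errors, proportions mediated and
    Benjamini-Hochberg screening across a mediator panel. Includes a
    synthetic GWAS summary-statistics generator so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
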