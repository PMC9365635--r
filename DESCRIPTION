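Package: mrphenome
Title: Bidirectional Phenome-Wide Mendelian Randomization Screens
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for phenome-wide two-sample Mendelian randomization (MR)
    screens against a focal disease outcome such as atrial fibrillation.
    Provides summary-statistics input and allele harmonization, rescaling of
    linear-model betas for binary traits to the log-odds scale, greedy LD
    clumping with proxy substitution, cis-pQTL instrument selection for
    proteins, Steiger directionality filtering, a five-method univariable MR
    estimator suite (Wald ratio, inverse-variance weighted, MR-Egger,
    weighted median, simple and weighted mode), a three-stage robustness
    verdict with Bonferroni control, Bayesian colocalization via approximate
    Bayes factors, multivariable MR with conditional F statistics, and a
    synthetic summary-statistics generator with known ground truth so every
    stage is testable without external GWAS downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
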