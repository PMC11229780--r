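Package: mrmediate
Title: Two-Sample Mendelian Randomization and Mediation Analysis for
    GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection (p-value thresholding, greedy
    LD clumping, F-statistic filtering), allele harmonization with
    palindromic-SNP handling, univariable causal-effect estimators (Wald
    ratio, inverse-variance weighted with multiplicative random effects,
    maximum likelihood, weighted median, MR-Egger), a sensitivity suite
    (Cochran's Q, leave-one-out, MR-PRESSO outlier detection, Steiger
    directionality, approximate-Bayes-factor colocalization), and mediation
    decomposition by two-step MR (product of coefficients with delta-method
    standard errors) and multivariable MR (difference in coefficients),
    with proportion-mediated reporting and Benjamini-Hochberg control.
    Includes a summary-level GWAS simulator with known structural truth for
    calibration and recovery studies, and a pipeline driver that runs the
    forward screen, reverse MR, and mediation stages from a config file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
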