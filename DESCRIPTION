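Package: causalmr
Title: Two-Sample Mendelian Randomization with Sensitivity and Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection (p-value thresholding, greedy LD clumping,
    F-statistic filtering, confounder exclusion), allele harmonization with
    palindromic-variant resolution, causal estimation by inverse-variance
    weighting, MR-Egger regression, the weighted median, and multivariable MR,
    sensitivity analysis (Cochran's Q, Egger intercept, MR-PRESSO global,
    outlier and distortion tests), a four-criterion mediator screen with
    product-of-coefficients mediation proportions, a bidirectional study
    orchestrator, and a summary-level GWAS simulator with planted causal
    structure for calibration and recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
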