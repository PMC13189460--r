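Package: mrmediate
Title: Two-Sample Mendelian Randomization Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-step Mendelian randomization (MR) mediation
    analysis from genome-wide association study (GWAS) summary statistics:
    instrument selection (p-value thresholding, windowed greedy linkage
    disequilibrium clumping, F-statistic filtering), allele harmonization
    with palindromic-variant handling, five causal-effect estimators
    (inverse-variance weighted, MR-Egger, weighted median, simple and
    weighted mode), heterogeneity and pleiotropy diagnostics (Cochran's Q,
    Egger intercept, leave-one-out), the product-of-coefficients mediation
    decomposition with retention criteria, a screening pipeline over trait
    grids, and a summary-statistics simulator with known causal truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
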