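Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and harmonizing summary-statistic panels,
    instrument selection (p-value threshold, greedy LD clumping,
    F-statistic weak-instrument filtering), five causal-effect estimators
    (inverse-variance weighted, MR-Egger, weighted median, simple and
    weighted mode), sensitivity diagnostics (Cochran's Q, Egger intercept,
    MR-PRESSO outlier detection, leave-one-out), and two-step mediation
    analysis by the product-of-coefficients method with delta-method or
    Monte-Carlo confidence intervals. Includes a synthetic GWAS
    summary-statistics generator with known causal structure so the whole
    pipeline can be exercised and validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
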