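Package: hcymr
Title: Two-Sample Mendelian Randomization of Plasma Homocysteine and
    Liver Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    summary-level GWAS data: reading and harmonizing exposure/outcome
    association tables, instrument selection by significance thresholding,
    local LD pruning and explicit exclusion lists, and causal-effect
    estimation by per-SNP Wald ratios combined with inverse-variance
    weighting (fixed and multiplicative random effects), the weighted-median
    estimator with parametric-bootstrap standard errors, MR-Egger regression
    with its pleiotropy intercept test, and an MR-PRESSO-style global
    heterogeneity, per-SNP outlier and distortion analysis. Ships the
    12-instrument plasma-homocysteine dataset with FinnGen NAFLD, NASH and
    cirrhosis outcomes as a packaged fixture, and a synthetic
    summary-statistics generator for validating every estimator against
    known generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
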