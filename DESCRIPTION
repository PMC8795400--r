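Package: exprmr
Title: Two-Sample Mendelian Randomization of Gene Expression on Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end two-sample Mendelian randomization (MR) toolkit for
    estimating the causal effect of gene expression on a binary disease
    outcome from summary statistics. Builds genetic instruments from cis-eQTL
    summary data (genome-wide significance filtering, top-SNP selection, LD
    clumping against a reference panel), harmonises exposure and outcome
    effect alleles, and computes Wald-ratio, inverse-variance-weighted,
    MR-Egger, weighted-median and weighted-mode causal estimates with
    Cochran's Q, leave-one-out and funnel diagnostics. Includes
    approximate-Bayes-factor colocalization of eQTL and GWAS signals,
    analytic power and instrument-strength (R-squared, F-statistic)
    calculations for case-control outcomes, and a simulation module that
    generates linked exposure/outcome summary statistics with known causal
    ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
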