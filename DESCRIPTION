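Package: mrivw
Title: Two-Sample Mendelian Randomization with Wald Ratios and
    Inverse-Variance Weighting
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS
    summary statistics: reading and harmonizing per-variant association
    records, per-variant Wald ratio causal estimates, fixed- and
    random-effects inverse-variance weighted pooling with Cochran's Q
    heterogeneity and leave-one-out sensitivity analyses,
    weak-instrument F-statistics, conversion of linear-mixed-model
    effect estimates on binary traits to the log-odds scale, and a
    weighted genetic-risk-score pleiotropy scan with
    direction-aligned z-scores and Benjamini-Hochberg FDR control.
    Includes a synthetic GWAS data generator (Hardy-Weinberg genotypes,
    rank-based inverse-normal-transformed exposures, logistic binary
    outcomes, configurable exposure/outcome sample overlap) so every
    pipeline stage is testable without individual-level cohort data,
    and a packaged verification of a published anti-Mullerian hormone
    to cardiometabolic disease analysis from its printed per-variant
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'sumstats.R'
    'harmonize.R'
    'mr-core.R'
    'mrivw-package.R'
    'pleiotropy.R'
    'scales.R'
    'reproduce.R'
    'synthetic.R'
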