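Package: mc4rbias
Title: Functional Characterization of MC4R Variants and Meta-Regression of
    BMI Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links cell-based measurements of melanocortin 4 receptor (MC4R)
    signaling (maximal cAMP production and beta-arrestin recruitment,
    quantified from time-resolved luminescence traces) to population genetic
    association estimates for body mass index and obesity-related outcomes.
    Provides quantification of assay traces (baseline-corrected AUC, two-point
    mock/wild-type normalization, single-sample t tests, gain/loss-of-function
    calls), geometric-mean signaling-bias ratios, per-variant and carrier-group
    regression association, fixed-effect inverse-variance pooling, and a
    random-effects meta-regression with REML between-variant variance and
    percent variance explained, together with a fully seeded synthetic-data
    generator so the complete pipeline runs without access to individual-level
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
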