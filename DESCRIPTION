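Package: hbcalib
Title: Calibration of In Silico Pathogenicity Predictors for Globin Gene Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and calibrating in silico variant-effect
    predictors on single nucleotide variants in the globin genes (HBA1, HBA2,
    HBB) for use as computational evidence (PP3/BP4) under the ACMG/AMP
    variant-interpretation framework. Implements confusion-matrix diagnostics
    with likelihood ratios and log-method confidence intervals, MCC-optimal
    binary threshold selection, the search for non-overlapping pathogenic and
    benign threshold pairs mapped to Bayesian evidence strengths, splicing
    predictor evaluation (SpliceAI delta scores, MaxEntScan Diff/Per rules),
    tool concordance analysis, mechanical consensus annotation rules, and a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
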