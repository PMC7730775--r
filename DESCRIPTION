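Package: coinca
Title: Coincidence Analysis for Configurational Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers redundancy-free Boolean models linking configurations of
    discrete factor values to an outcome, following the coincidence-analysis
    family of configurational comparative methods. Provides calibration helpers
    for turning raw case-level measurements into crisp multi-value factors
    (thresholding, ordinal recoding, meta-factor aggregation, variation
    screening), exact-rational consistency and coverage fit measures, a
    bottom-up search for minimal sufficient conditions and atomic and complex
    solution formulas, common-core extraction across ambiguous model sets, a
    fit-robustness threshold scan, a ground-truth simulator for method
    validation, and a reproduction pipeline for a published county-level
    HPV catch-up vaccination study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
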