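Package: periogrm
Title: Optimal Periodontal Examination Site Selection via Graded Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Item response theory tools for periodontal epidemiology. Fits
    Samejima's graded response model to site-level full-mouth periodontal
    charts (clinical attachment level, probing depth, bleeding on probing,
    plaque index, tooth mobility) by marginal maximum likelihood EM, computes
    item information functions and their integrals, and runs a stepwise
    item-information site-reduction procedure that narrows 168 full-mouth
    examination sites down to a 6-variable, 12-site partial-examination
    protocol. Includes evaluation tools (ROC analysis with an equal-error
    cutoff rule, GLM link selection by AIC, CDC-AAP case classification, a
    PD/BOP-based community periodontal index comparator, and partial-exam
    bias metrics) and a calibrated synthetic full-mouth cohort generator for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
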