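Package: inhalertech
Title: Hybrid Rule and Transformer Detection of Inhaler-Technique
    Documentation in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies documentation of asthma inhaler-technique review or
    teaching in the free text of clinical notes.  Provides a keyword-combination
    rule engine over the History of Present Illness and Impression/Report/Plan
    sections, distant supervision (rule-generated weak labels) for building
    large training sets, a cost-sensitive transformer sentence classifier with
    a triangular cyclical learning-rate schedule, post-hoc rule correction of
    model predictions (hybrid model), document-level F-beta evaluation, and a
    synthetic clinical-note generator so that every pipeline stage is testable
    without protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
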