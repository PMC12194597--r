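Package: vppflow
Title: Data-Driven Design and Evaluation of Emergency Department Vertical Patient Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating a data-driven vertical patient
    pathway (VPP) in an emergency department. Provides a synthetic ED encounter
    generator with a known bed-need mechanism, tiered outcome labeling, a
    random-forest bed-need risk model, closed-form M/M/1 and M/M/1-with-
    exponential-vacations queueing analysis with misclassification-aware
    routing-threshold optimization, a validating discrete-event simulator with
    alternative flow designs (fast track, physician in triage), distillation of
    per-state optimal routing into an interpretable decision-tree protocol, and
    before/after log-length-of-stay and return-rate evaluation models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    ranger,
    rpart,
    pROC,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
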