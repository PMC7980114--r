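Package: pulseman
Title: Wearable Patient Monitoring and Counterfactual Well-Being Recommendations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for data-driven self-management support in chronic heart
    failure built around four patient-monitoring components: cuffless blood
    pressure estimation from wrist photoplethysmography (PPG) with
    template-based signal-quality screening, physical-activity recognition
    from wrist tri-axial acceleration, psychophysiological profile
    recognition from speech prosody and heart-rate variability, and a
    two-objective NSGA-II counterfactual recommender that searches for
    minimal admissible modifications of modifiable features predicted to
    flip a patient's feeling of health from bad to good. Includes
    seed-deterministic synthetic-data generators with ground truth for every
    component, leave-one-subject-out and chronological personalized
    evaluation harnesses, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    ranger,
    rpart,
    e1071,
    nnet,
    caret,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
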