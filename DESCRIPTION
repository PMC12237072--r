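Package: birdpool
Title: Integrated Distribution Models Pooling Acoustic Surveys and Citizen-Science Checklists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for modeling encounter rate and occupancy of
    rainforest birds along a floodplain-terra firme habitat gradient by pooling
    structured acoustic-survey detections with semi-structured citizen-science
    checklists. Implements classifier confidence-score calibration with an
    fpr-constrained acceptance threshold, zero-filling, spatiotemporal
    subsampling, synthetic minority-class oversampling, calibrated bootstrapped
    random-forest encounter models, and Bayesian single-source and integrated
    occupancy models with staged predictor selection, WAIC comparison and
    cumulative-detectability filtering. Includes a synthetic-data generator
    emulating a height-above-nearest-drainage (HAND) landscape, river-biased
    citizen effort, and hour-scale acoustic sampling with label-dependent
    classifier scores, so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    ranger,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
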