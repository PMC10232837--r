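Package: preictal
Title: End-to-End Seizure Prediction from Scalp EEG with an LSTM Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end epileptic seizure prediction pipeline for
    multichannel scalp EEG. Continuous recordings (EDF) are labeled into
    preictal, ictal, postictal and interictal stages from seizure
    annotations, band-pass filtered into the five standard EEG bands with
    zero-phase FIR filters, split into non-overlapping 5-second windows,
    and classified by a long short-term memory (LSTM) network trained on
    the gamma-band signal directly, with no hand-crafted features.
    Sample-level predictions are fused into segment-level decisions by
    majority-vote rules and into event-level alarms scored under the
    seizure-occurrence-period / seizure-prediction-horizon (SOP/SPH)
    framework, including the false prediction rate, warning times and a
    random-predictor significance test. A synthetic EEG generator with
    stage-dependent band power makes the whole pipeline testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
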