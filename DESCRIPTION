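Package: raceRP
Title: Race-to-Threshold Accumulator Modelling and Readiness-Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates and fits a dual-component race-to-threshold leaky
    stochastic accumulator model of deliberate versus arbitrary decisions,
    predicts the movement-locked readiness potential (RP) implied by the
    model, and provides the accompanying EEG analysis operators: zero-phase
    FIR filtering, artifact rejection, trial exclusion, stimulus- and
    response-locked epoching, RP and lateralized readiness potential (LRP)
    measurement, average- and single-trial trend regression, cluster-based
    permutation testing against zero, radial-EOG saccade counting, and a
    behavioral consistency grade. A synthetic behavior-plus-EEG generator
    with gamma reaction times, 1/f noise and injected pre-movement
    components makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    MASS,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
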