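Package: mukin
Title: Wrist Kinematics Decoding from Motor Unit Discharge Timings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proportional myoelectric control research: predicts
    wrist joint angles for three degrees of freedom from motor unit discharge
    timings obtained by high-density surface EMG decomposition, and compares
    them against interference-EMG time-domain features under repeated
    three-fold leave-one-ramp-out cross-validation. Includes a motor neuron
    pool / surface EMG simulator (triangular kinematic cues, recruitment
    ordered pools driven by a kinematics-derived common drive, multichannel
    motor unit action potential templates, configurable decomposition-error
    corruption), windowed time-domain and decomposed-spike-count feature
    extraction with PCA, spike-triggered-average template estimation and
    residual EMG computation, and a model-based dimensionality reduction that
    maps each unit's spike count to a synaptic-input proxy by robust bisquare
    regression and pools units per degree of freedom with a recursive median.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
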