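Package: shemon
Title: Skin-Wearable Cardiac and Activity Monitoring Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for wireless skin-wearable single-lead
    electrocardiography and inertial motion monitoring. Provides QRS detection
    (a Pan-Tompkins variant), heart-rate and ECG-derived respiratory-rate
    estimation, a windowed signal-to-noise metric with median-filter noise
    isolation, a sequence-to-sequence 1-D convolutional network for per-sample
    ECG annotation, a residual 1-D convolutional network for activity
    recognition from 6-axis inertial data, synthetic ECG/IMU generators with
    exact ground truth, the thin-film conformal-contact adhesion criterion for
    electrode laminates on rough skin, and a streaming monitor that fuses all
    outputs into timestamped events with alert flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
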