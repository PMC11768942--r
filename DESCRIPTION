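Package: rppgtime
Title: Timing Correction and Heart-Rate Estimation for Remote Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Low-complexity timing correction for irregularly sampled and lossy
    remote-photoplethysmography (rPPG) signals. Provides linear, natural
    cubic-spline and cascaded integrator-comb (CIC) filter interpolation onto a
    uniform grid, an FFT dominant-frequency heart-rate estimator for the
    resting band, synthetic signal generators with frame-drop and timing-jitter
    corruption models, and Monte-Carlo benchmarking of reconstruction and
    heart-rate error under varying corruption levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
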