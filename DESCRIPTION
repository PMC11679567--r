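Package: pulseband
Title: Multi-Band Recovery of Blood Volume Pulse from Facial-Video
    Spatio-Temporal Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lightweight pipeline for remote photoplethysmography (rPPG):
    converts region-mean RGB time series extracted from facial video into
    normalized modified-YUV spatio-temporal maps, decomposes them into
    frequency bands with an orthonormal DCT, and recovers the blood volume
    pulse (BVP) waveform with a small multi-branch 1-D convolutional network
    featuring temporal multiscale convolutions and spectrum self-attention,
    trained with a negative-Pearson loss and a heart-rate-stratified
    over-sampling scheme. Heart rate and heart rate variability (LF/HF in
    normalized units) are derived from the recovered waveform. A seeded
    synthetic rPPG generator provides ground-truth pulse waveforms with
    illumination drift, motion artifacts and white noise so that every stage
    can be trained and validated without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
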