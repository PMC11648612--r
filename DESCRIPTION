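Package: sonoresponse
Title: Ultrasound Neuromodulation Dosimetry and Evoked-Response Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for ultrasound neuromodulation
    experiments: burst-pulse-train dosimetry (I_SPPA, per-stimulus energy,
    adiabatic heating bound), stimulus-evoked calcium-transient
    quantification (dF/F0 normalization and post-stimulus area under the
    curve) from per-ROI fluorescence time series, peristimulus time
    histograms of multiunit activity, and jitter-surrogate null testing
    with pointwise and global significance bands for detecting
    stimulus-locked modulation of population spiking. Includes synthetic
    generators for GCaMP-like calcium traces, inhomogeneous Poisson spike
    trains, and extracellular voltage so every stage is testable without
    experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
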