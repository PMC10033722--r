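Package: ecgvelocity
Title: ECG Signal Propagation Velocity from Two-Channel Cross-Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the propagation velocity of the electrocardiogram (ECG)
    treated as a low-frequency endogenous electromagnetic wave travelling
    through body tissue. Provides a dispersive tissue model that converts a
    relative-permittivity spectrum into a frequency-dependent phase velocity,
    a seeded two-channel ECG simulator with known implanted inter-electrode
    delay (fractional frequency-domain delays, white noise at a target
    signal-to-noise ratio, gated power-line distortion), preprocessing
    (rolling-mean smoothing, steepest-slope QRS triggering, SNR estimation,
    quality gating), FFT and direct cross-correlation lag estimators with a
    theory-bounded lag window, velocity summary statistics, and a small
    command-line interface for simulation, estimation and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
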