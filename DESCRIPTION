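Package: vwmflow
Title: Flow-Dysfunction Screening from Radar-Sensed Vascular Wall Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for non-invasive surveillance of
    arteriovenous fistula (AVF) access flow in hemodialysis patients. Models a
    pulse-radar sensor that demodulates vessel-wall displacement into a
    baseband signal, generates synthetic patient cohorts with
    turbulence-distorted wall-motion waveforms under low-flow conditions,
    replicates the acquisition chain (Hamming-window FIR band-pass, 64 Hz
    device rate), extracts harmonic-ratio features from FFT spectra, screens
    features with two-sample t-tests, and classifies flow dysfunction with a
    radial-basis-function support vector machine evaluated by stratified
    k-fold cross-validation and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
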