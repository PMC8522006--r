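Package: earsleep
Title: Ear-EEG Sleep Staging: Virtual Montages, Grapho-Element
    Correlation Topography and Hypnogram Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for sleep EEG recorded with a C-shaped
    around-the-ear electrode array (cEEGrid) alongside a minimal frontal
    polysomnography reference (Fpz plus two EOG channels). Builds
    virtual PSG-style derivations as linear combinations of ear
    electrodes, conditions the signals with a zero-phase Butterworth
    bandpass and decimation, correlates annotated K-complex and
    sleep-spindle epochs against every single and bipolar ear-channel
    combination with Fisher-Z averaging, and quantifies hypnogram
    agreement with multi-class and one-vs-rest Cohen's kappa, asymptotic
    standard errors, Landis-Koch labels and paired one-tailed t-tests.
    A synthetic polysomnography generator (stage-structured Markov
    hypnograms, stage-dependent spectra, frontal-source grapho-elements
    mixed onto all channels, imperfect second scorers) makes the full
    pipeline testable end to end. Includes EDF and CSV readers/writers
    for recordings, hypnograms, event annotations and confusion
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
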