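Package: ffrscore
Title: Neural Coding of Consonants in Noise from Frequency-Following Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for speech-evoked
    frequency-following responses (FFR, also known as the cABR) recorded
    while a consonant-vowel syllable is presented in multi-talker babble.
    Provides a formant-cascade synthesizer for the 170 ms [da] target and a
    speech-shaped babble surrogate with SNR-controlled mixing; a synthetic
    cohort generator that plants known response templates and child-level
    brain-behavior couplings; the standard offline preprocessing chain
    (frequency-domain low-frequency boost, zero-phase Butterworth bandpass,
    epoching, baselining, amplitude artifact rejection, polarity-added
    averaging); the three neural-coding metric families (transition peak
    latencies, first-formant harmonic amplitudes, split-half response
    stability with Fisher z); the two-block hierarchical regression that
    yields a frozen "consonants-in-noise score" transferable to new cohorts
    without refitting; and downstream correlation, discriminant, and ROC
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    pROC,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
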