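Package: audbattery
Title: Adaptive Psychoacoustic Test Battery Simulation and Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing a suprathreshold auditory
    psychophysics battery: stimulus synthesis for temporal-gap, frequency
    modulation, spectro-temporal modulation, notched-noise, and speech-on-speech
    spatial-release assessments; two-stage transformed up-down (two-down one-up)
    adaptive staircases with unequal step sizes and their analytic convergence
    targets; progressive target-to-masker tracking; parametric simulated
    observers for end-to-end verification; and a test-retest reliability
    pipeline (Bland-Altman limits of agreement, paired statistics, composite
    z-scores, Cronbach's alpha) together with a seeded two-session synthetic
    cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
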