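Package: speechvar
Title: Speech Production Variability Measures for Clinical Speech Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a battery of speech-production variability measures
    (voice-onset-time variability, vowel-duration variability, speech-rate
    variability from diadochokinetic and connected speech, formant dispersion,
    vowel-category overlap, and pausing measures) from time-aligned segment
    data such as Praat TextGrid interval tiers, and runs covariate-adjusted
    two-group comparisons, within-group validity correlations,
    modality-stratified analyses, and Fisher-z power calculations for studies
    of speech motor variability in clinical populations. Includes a fully
    seeded synthetic cohort generator that emulates the segment-level
    structure of diadochokinetic, read, and spontaneous speech tasks together
    with clinical and motor covariates, so every pipeline stage can be
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
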