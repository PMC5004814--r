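Package: vibrotact
Title: Spike-Train Analysis of S1 Coding During Whisker Vibrotactile
    Sequence Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse trial-aligned somatosensory cortex (S1) spike
    trains recorded while rats discriminate rapid whisker impulse sequences.
    Provides parametric construction of panel stimulus waveforms and
    integrated-speed regressors, a seeded inhomogeneous-Poisson synthetic
    session generator with ground-truth unit archetypes, post-sorting unit
    quality control, PSTH and permutation-based temporal-modulation testing,
    impulse-evoked response and adaptation metrics, choice-related firing
    analyses, integration-window regression classification of units into
    Fast/Medium/Slow response classes, one-vs-all logistic population decoding
    of stimulus identity and behavioral choice with rate-normalized and
    time-scrambled controls, and signal-detection behavioral summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
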