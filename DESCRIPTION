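Package: awtsim
Title: Simulation and Analysis of the Attention-Window Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico pipeline for the Attention-Window Task (AWT), a
    dual-stimulus psychophysical paradigm that measures the maximum spatial
    spread of visual attention. The package generates balanced trial
    schedules for the basic task and its cue-validity, stimulus-onset
    asynchrony and stimulus-complexity variants, simulates parametric
    synthetic observers with logistic identification profiles, scores
    trial records with the ascending 75 percent accuracy criterion,
    reconstructs the attention-window polygon per meridian, and runs
    two-way repeated-measures ANOVAs with Mauchly sphericity diagnostics,
    Greenhouse-Geisser correction, partial eta squared and
    Bonferroni-corrected pairwise comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    utils,
    stats
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
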