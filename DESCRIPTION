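Package: gazelex
Title: Eye-Tracking Analysis of Lexical Retrieval Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing screen-based eye-tracking recordings
    from picture-naming (lexical retrieval) tasks. Raw gaze samples are
    classified into fixations and saccades with a velocity-threshold (I-VT)
    algorithm, restricted to a central area of interest, and summarised into
    six per-trial oculomotor metrics (fixation count and duration, saccade
    count, duration, scanpath length and summed amplitude). A grid-based
    spatial layer computes Shannon entropy, spatial dispersion, grid
    occupancy, transition density and the Clark-Evans nearest-neighbor
    index of fixation patterns; a statistics layer provides Mann-Whitney U
    comparisons with tie-corrected normal approximation, Pearson
    correlations, two-way mixed ANOVA with Bonferroni post-hocs, and
    post-hoc power analyses (noncentral t and F, Fisher z). A calibrated
    two-cohort synthetic gaze generator makes every stage testable without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
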