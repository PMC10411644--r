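Package: facegaze
Title: Semantic Target Effects on Saccade Dynamics in Free Viewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the semantic category of an upcoming
    saccade target (a face versus an inanimate object) modulates free-viewing
    gaze dynamics in complex scenes. Segments 2 kHz gaze streams into
    saccades, fixations and blinks, applies a documented exclusion cascade,
    labels fixations against pixel-mask scene annotations, builds
    incoming-saccade / intermediate-fixation / target-saccade / target-fixation
    event series with eight kinematic and low-level predictors, and fits
    linear mixed-effects models with AIC-based selection, binned two-way
    ANOVAs and Holm-Bonferroni paired post hoc tests. Includes a synthetic
    scanpath generator with planted effects so every stage is testable
    without eye-tracking recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
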