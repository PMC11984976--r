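Package: emgfmg
Title: Limb-Position and Load Effects on EMG and FMG Hand-Gesture
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for studying how limb position and
    grasped load affect hand-gesture classification from surface
    electromyography (EMG), force myography (FMG), and their stacked
    fusion. Provides a seeded synthetic-session generator emulating
    8-channel EMG plus 8-channel FMG recordings of a grasp-and-hold
    protocol, contraction-phase segmentation with sliding windows,
    Hudgins time-domain feature extraction, linear discriminant analysis
    with leave-one-repetition-out cross-validation, three cross-condition
    evaluation designs (full condition classification, neutral versus
    varying conditions, and cross-position/cross-load transfer), and a
    statistical comparison layer based on random-intercept linear
    mixed-effects models with Benjamini-Hochberg adjusted pairwise
    contrasts of estimated marginal means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    emmeans,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
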