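Package: flumetrack
Title: Video-Based Quantification of Benthic Grazer Foraging and Its
    Downstream Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify foraging behaviour of colour-marked benthic
    grazers from time-lapse flume imagery and to run the downstream
    analyses of a factorial nutrient-by-grazing experiment: colour-blob
    detection with sub-pixel centroids, multi-object track linking by
    optimal Euclidean assignment, movement-state classification
    (resting/slow/fast), grazed-area segmentation with pixel-to-cm2
    calibration, CHEMTAX-style iterative pigment-ratio unmixing of algal
    community composition, and the stoichiometric and statistical layer
    (molar C:P, grazing rates, t-tests, two-way ANOVA with Tukey HSD).
    Includes a ground-truthed synthetic scene generator that emulates the
    experimental set-up (marked grazers on periphyton-covered tiles with
    progressive biofilm depletion) so every estimator can be validated
    against known trajectories, behavioural states, grazed masks and
    community compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    png,
    yaml,
    car,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
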