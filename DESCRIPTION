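Package: zebraphen
Title: Behavioral and Bioenergetic Phenotyping of Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for larval zebrafish phenotyping
    experiments: noninvasive redox-fluorescence genotype sorting by plate
    quartiles, light-flash-response locomotion metrics from activity-camera
    time series, eye-convergence-gated prey-capture hunting-event detection
    with rolling-median rotifer-depletion curves, tail-bout segmentation and
    kinematic summaries, oxygen-consumption-rate decomposition into basal,
    maximal and nonmitochondrial components, and the accompanying
    statistical and survival analyses. Includes synthetic-data generators
    with machine-readable ground truth for every input modality, so each
    detector and summary can be validated without access to rig hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
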