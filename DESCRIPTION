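Package: polefocus
Title: Simulation and Quantification of Polar Protein Cluster Dynamics in
    Bacterial Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the spatiotemporal dynamics of polar protein
    clusters (such as the general PTS protein Enzyme I) in rod-shaped
    bacteria from two- or three-channel time-lapse fluorescence microscopy.
    Provides a ground-truthed synthetic microscopy generator (rod-shaped
    cells with a diffuse cytoplasmic pool and compact polar foci, growth and
    division with asymmetric cluster inheritance, stochastic cluster
    nucleation and gradual dispersal, photobleaching with exchange-driven
    recovery, and an activity-reporter channel), together with the matching
    analysis pipeline: cell segmentation and geometry, focus detection with
    top-hat background homogenization, per-cell mean and
    standard-deviation-intensity statistics, nearest-neighbour focus
    tracking and speed measurement, four-way localization-pattern
    classification, formation and dispersal event detection, sister-cell
    inheritance scoring, FRAP recovery normalization and exponential
    fitting, and correlation and ANOVA statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
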