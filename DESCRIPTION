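Package: MotionMorph
Title: Motion-Based Automatic Body-Length Measurement of Soft-Bodied
    Arthropods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the body length of a single soft-bodied arthropod
    (e.g. the springtail Folsomia candida) from a short series of still
    frames taken on a fixed backlit background. Moving animals are
    segmented by secondary difference images (the pixelwise minimum of
    the absolute differences of each interior frame with its two
    neighbours), thresholded, and reduced to particles whose
    moment-fitted ellipse major axis is filtered by a critical ratio,
    mapped through a linear calibration, and averaged into one length
    per individual. Includes the two calibration-derivation procedures
    (least-squares fit of manual lengths on the major axis, and the
    critical ratio from posture annotations), a seeded synthetic-scene
    generator with ground truth for validation, tabular export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Visualization, CellBasedAssays
RoxygenNote: 7.3.3
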