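Package: seedlingvigor
Title: Seedling Length Ground Truth and Vitality Scoring from Instance Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for recovering physical seedling lengths from top-down
    instance-segmentation masks and for scoring treatment-level growth
    vitality. Implements contour extraction and pixel-perimeter measurement,
    empirical ring-stratified correction of radial (pincushion) lens
    distortion anchored at a central calibration seedling, phototropic tilt
    foreshortening correction with lighting-prior angle smoothing,
    age-dependent confidence filtering, and pixel-to-centimetre scaling.
    Treatment groups are summarised by a dual-index vitality score (static:
    mean length; dynamic: fitted growth rate) with max-normalised equal-weight
    aggregation into comprehensive percentage shares. A seeded synthetic-scene
    generator emulates the imaging rig (1600 px frame, 25 cm box, 7 x 7
    planting grid, pincushion warp, phototropic tilt, 50-minute capture
    interval over 90 h) with exact ground truth, so every stage of the
    pipeline is testable end to end. Detection-evaluation utilities (mask IoU,
    COCO-style average precision) and convolution-layer complexity formulas
    are included as stand-alone helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    png,
    EBImage,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
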