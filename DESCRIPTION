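Package: biofilmwet
Title: Wettability-Based In-Situ Biofilm Detection from Stained-Dish Images
    and Liquid-Squeezing Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies crystal-violet-stained biofilm coverage from scanner
    images of petri dishes (display-gamma decompensation, optical-density
    calibration against neutral-density standards, centre-half-radius region
    of interest, threshold-based percent stained area) and assesses surface
    wettability from liquid-squeezing videos (dry-area segmentation,
    equivalent-circle diameter time series, mean squeezed and residual
    diameter indexes, oscillation-frequency estimation). Also provides a
    captive-bubble contact-angle estimator by circular-arc fitting, the gated
    F-test/Student-Welch two-sample comparison used for group statistics, and
    seeded synthetic phantom generators (stained dishes, squeeze videos,
    bubble silhouettes) with stored ground truth so every stage is testable
    without raw laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
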