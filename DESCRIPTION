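Package: woundsim
Title: Agent-Based Simulation and Track Analysis of Partial-Thickness
    Scratch-Wound Re-Epithelialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates basal keratinocyte sheet migration into a narrow
    scratch wound (wound-ward drift with jamming at the wound edge, hair
    follicle obstacles, zone-dependent cell-cycle progression) and provides
    the quantitative pipeline used on intravital time-lapse data: track
    input/output and nearest-neighbour linking, fiducial-based drift
    correction, per-track motility metrics (speed, persistence,
    directionality, distance-binned velocities), Delaunay neighbour-retention
    statistics, synthetic membrane and Fucci reporter rendering, classical
    membrane segmentation with size and circularity filters, and zone-binned
    proliferation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    interp,
    dplyr,
    EBImage,
    FNN,
    ggplot2,
    jsonlite,
    RANN,
    readr,
    tiff,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
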