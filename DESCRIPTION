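Package: moonwatch
Title: Automated Moon-Watching for Quantifying Nocturnal Bird Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software toolkit for lunar moon-watching, the classical method
    of quantifying nocturnal bird migration by counting silhouettes crossing
    the moon's disk through a telescope. Provides a synthetic lunar-video
    simulator with exact ground truth, a closed-loop visual-servo moon
    tracker driving a simulated alt-azimuth mount, frame-timestamp logging
    and reconstruction for cameras with imprecise frame rates, automated
    silhouette detection and track linking on the lunar disk, and analytics:
    compass flight directions from image tracks via a projection model, body
    orientation and wind-drift angles, apparent-size distance estimates, a
    direction rose with circular statistics, and a Lowery-style migration
    traffic rate with an explicit elliptical viewing-gate correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    optparse,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
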