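Package: footacs
Title: Automatic Anatomical Coordinate Systems for Foot and Ankle Bone Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns anatomical coordinate systems (medial-lateral,
    anterior-posterior, superior-inferior axes plus an origin) to triangle
    surface meshes of the fourteen major foot and ankle bones. Bones in any
    pose are mirrored to left-side anatomy when needed, rigidly aligned to a
    pre-oriented template by iterative closest point registration, partitioned
    into equal-width volumetric regions per anatomical plane, and the region
    centroids define the primary, secondary and tertiary axes. Includes
    readers and writers for STL, PLY, VTK, keyword-format shell meshes and
    correspondence-particle files, comparison metrics between coordinate
    systems (per-axis angle differences, correspondence-particle projection
    distances, one-way ANOVA with Tukey post hoc), a synthetic bone generator
    with known ground-truth axes for validation, and a batch driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
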