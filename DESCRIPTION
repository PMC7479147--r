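Package: pgcquant
Title: Quantification of Cortical Polarity and Cell-Cluster Dispersal in 4D Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how cells disperse from embryonic clusters in
    multi-channel time-lapse Z-stacks, modelled on the image analysis used to
    study Drosophila primordial germ cell (PGC) cluster dispersal. Provides
    radial intensity profiling around a cluster centroid with per-depth
    background normalization, automatic detection of polarized cortical
    regions with orientation and reorientation-event statistics,
    posterior-intensity time courses, shape descriptors (circularity,
    membrane-to-cytoplasm ratio), 3D track metrics (speed, straightness,
    distance from a reference, transmigration counts), rank-sum and exact
    proportion tests, and a synthetic 4D fluorescence-microscopy generator
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
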