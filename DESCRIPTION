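Package: cordmorph
Title: Surface-Based Morphometry of the Cervical Spinal Cord
Version: 0.1.0
Authors@R:
    person("Morphometry", "Maintainers", email = "cordmorph@example.org",
           role = c("aut", "cre"))
Description: Tools for surface-based morphometry of the cervical spinal cord
    from T2-weighted-like volumes and binary cord masks: cropping and cubic
    resampling to a working resolution, double-threshold cord segmentation,
    cord straightening and length standardization, radial-distance and
    cross-sectional-area profiling, permutation-based group atrophy mapping
    with a supra-significance threshold, Spearman correlation maps against
    clinical scores, and a synthetic cord-phantom cohort generator with known
    ground-truth geometry for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
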