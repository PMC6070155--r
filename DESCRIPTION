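Package: sticcs
Title: Spatiotemporal Image Cross-Correlation Spectroscopy and Comet
    Tracking for Microtubule Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps microtubule and EB3 plus-end velocities in two-channel
    fluorescence time-lapse movies by spatiotemporal image cross-correlation
    spectroscopy (STICCS): temporal Fourier filtering of immobile structures,
    space-time correlation functions on an overlapping ROI/TOI voxel grid,
    flow vectors from correlation-peak translation, neighbourhood
    similarity filtering, and classification of explorative (cross-correlated)
    versus fiber-guided microtubule assembly. Includes a Laplacian-of-Gaussian
    plus linear-assignment comet tracker for EB3 growth metrics, per-cell and
    per-condition summary statistics, and a synthetic two-channel movie
    generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
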