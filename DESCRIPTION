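Package: chipdpcr
Title: Chamber-Array Digital PCR Simulation, Image Analysis and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for chamber-array digital PCR
    (dPCR) chips. Models Poisson partitioning of template molecules into a
    microfluidic array of nanolitre chambers, renders per-channel 16-bit
    fluorescence images with ground truth, recovers chamber calls from images
    by grid registration and two-class intensity thresholding, performs
    Poisson absolute quantification with Wilson-score confidence intervals,
    and carries out reference-gated multiplex mutation typing with
    mutation-rate estimation, dilution-series linearity analysis and
    limit-of-detection power simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
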