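Package: mechanops
Title: Mechano-Node-Pore Sensing of Single-Cell Mechanical Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for mechano-node-pore sensing (mechano-NPS), a
    four-terminal resistive-pulse technique that measures single-cell
    mechanical phenotypes in a microfluidic channel whose width alternates
    between wide nodes, narrow pores, and a long central contraction segment.
    Provides a forward simulator of current-versus-time traces with per-cell
    ground truth, pulse detection and sub-pulse segmentation, microsphere
    calibration of the channel's effective diameter, inversion of the Coulter
    blockade equation for free cell diameter, the oblate-spheroid deformation
    model, the dimensionless whole-cell deformability index (wCDI) with its
    Buckingham-pi decomposition, recovery-time classification, cortical
    tension from micropipette aspiration, and population-level analyses:
    normal-distribution overlap, expectation-maximization decomposition of
    lineage mixtures, and recovery-profile tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
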