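Package: AirySheet
Title: Simulation and Bead-Based Characterization of Airy-Beam Light-Sheet
    Microscopes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scalar-diffraction simulator for single- and two-photon
    light-sheet excitation fields shaped by a refractive cubic (Airy) phase
    mask, including polychromatic (ultrashort-pulse) excitation with material
    dispersion, and the companion bead-phantom characterization pipeline for
    inverted selective-plane-illumination (iSPIM) geometries: synthetic bead
    stack rendering, spot detection and tracking, scan-angle estimation,
    deskewing into detection coordinates, axial/lateral PSF extraction,
    resolution and field-of-view summaries, a light-sheet figure of merit,
    and Richardson-Lucy deconvolution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
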