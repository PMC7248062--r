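Package: woundstrain
Title: Non-Invasive Optical Quantification of Skin-Wound Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Point-tracking-based reconstruction of heterogeneous
    Green-Lagrange strain fields in stretched skin, wound-region
    deformability, functional wound length from piecewise-linear
    displacement regression, healing-rate computation on unevenly spaced
    time grids, and element-based collagen-density mapping from binary
    fiber masks. Includes a synthetic ground-truth generator (speckled
    sheet with a stiff circular inclusion under uniaxial extension, with
    a rate-dependent stiffness-contrast variant) used as the test bed,
    a normalized-cross-correlation point tracker with subpixel
    refinement, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    EBImage,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
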