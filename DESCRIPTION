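Package: mmdepth
Title: Depth-Resolved Imaging in Turbid Media by Mueller Matrix Polarimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrieving the depth of anisotropic fibrous inclusions
    embedded in isotropic scattering media from backscattering Mueller matrix
    images. Implements a dual-rotating-retarder polarimeter forward model and
    its least-squares reconstruction, the standard polarization basic parameter
    systems (Lu-Chipman polar decomposition, Cloude coherency decomposition,
    Mueller matrix transformation, rotation-invariant parameters, and the
    global-polarization Stokes ellipsoid), composite depth-sensitive
    polarization feature parameters, screening statistics for depth
    sensitivity, regression models for depth retrieval with cross-validation,
    two-dimensional depth mapping with zone statistics, and a tissue-phantom
    simulator with a Mie scattering-coefficient calculator.
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
    jsonlite,
    e1071,
    caret
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
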