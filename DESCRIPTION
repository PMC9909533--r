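Package: leafspec
Title: Non-Destructive Pesticide Residue Estimation from Leaf Spectra and
    Characteristic-Band Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric and machine-vision pipeline for estimating pesticide
    residue concentration on vegetable leaves without destructive chemistry.
    Implements spectral preprocessing (min-max normalization, Savitzky-Golay
    convolutional smoothing and derivatives, multiplicative scatter correction,
    mean centering), characteristic-wavelength selection by the correlation
    coefficient method combined with principal-component scoring coefficients,
    PLS1 calibration with Rc/SEC/Rp/SEP model comparison, leaf-image
    segmentation and RGB channel statistics at the characteristic band, and a
    small convolutional neural network regressor mapping image features to
    residue concentration (mg/kg). A synthetic-data module generates labeled
    reflectance spectra with a planted absorption band and leaf images with
    concentration-dependent channel statistics, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
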