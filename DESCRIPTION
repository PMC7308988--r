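Package: ncamsim
Title: Simulation and Analysis of Filtered NIR-Sensitive RGB Cameras for NDVI Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-models low-cost NIR-sensitive RGB cameras (long-pass and
    two-band-pass filtered) imaging corn plants, simulates a factorial
    greenhouse cohort with hyperspectral ground truth, and runs the full
    analysis chain: whiteboard calibration, vegetation-index and red-edge
    segmentation, channel-sum normalization, chemometric spectral
    preprocessing (absorbance transform, multiplicative scatter correction,
    mean centering), regression estimators (multiple linear regression,
    Matern-5/2 Gaussian process, quadratic-kernel support vector regression,
    NIPALS partial least squares) under leave-one-out cross-validation, and
    agreement evaluation (R squared, RMSE, MAE, MPE, Bland-Altman limits).
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
    e1071,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
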