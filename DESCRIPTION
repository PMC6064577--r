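Package: canopyhp
Title: Simulation and Error Analysis of Hemispherical Photography for
    Canopy Gap Fraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how sky-canopy border length, exposure errors
    and thresholding errors jointly determine the inaccuracy of canopy
    gap-fraction estimates from hemispherical photographs.  Provides a
    grid model-canopy generator with exact geometric ground truth, a
    radiometric camera simulator (exposure manipulation in stops,
    Gaussian optical blur, gamma tone mapping, circular analysis mask),
    greyness-histogram and thresholding operators, Sobel-based
    mixed-pixel-zone measurement, 10-90 percent edge-response sharpness,
    the exposure-thresholding-mismatch (ETM) framework built on a
    logistic exposure/optimal-threshold calibration, and zero-intercept
    regression with a slope-homogeneity F-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
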