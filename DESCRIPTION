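Package: nirlipidmap
Title: Label-Free Mapping of Fatty-Acid Chain Length and Saturation from
    Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free chemometric mapping of liver lipids from
    near-infrared (1000-1400 nm) hyperspectral images. Computes
    hydrocarbon-chain-length (HCL) and degree-of-saturation (DS) statistics
    from fatty-acid compositions by functional-group counting, converts
    raw/dark/white hyperspectral frames to standard-normal-variate (SNV)
    corrected absorbance spectra, calibrates support-vector regression
    models of total lipid content, HCL and DS with leave-one-out
    cross-validation, and renders per-pixel prediction maps, pseudo-color
    NIR images and HCL/DS scatter plots. Ships a synthetic scene generator
    that emulates diet-structured liver data so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    ggplot2,
    graphics,
    grDevices,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
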