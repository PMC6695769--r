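Package: vinespec
Title: On-the-Go VIS/SW-NIR Spectroscopy Pipeline for Grape Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for estimating grape berry composition (total
    soluble solids, anthocyanins, total polyphenols) from georeferenced
    visible/short-wave near-infrared reflectance spectra acquired on the go
    from a moving platform in the vineyard. Provides S4 containers for
    spectral streams, cosine-similarity filtering of grape-cluster spectra
    against a reference signature, per-block averaging, scatter-correction
    and derivative pre-processing (SNV, detrend, Savitzky-Golay), PCA-based
    Q-residual and Hotelling T-squared outlier screening, NIPALS partial
    least squares calibration with venetian-blinds cross-validation, and
    multilevel B-spline surface interpolation for vineyard prediction maps.
    A synthetic vineyard generator emulates the field campaign (layout,
    block chemistry with spatial autocorrelation, class-labelled spectral
    streams) so that every stage is testable offline and parameter recovery
    is measurable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
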