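Package: zcuv
Title: Zero-Crossing Derivative UV Spectrophotometry for Binary Mixture Assay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation-backed toolkit for zero-crossing derivative
    UV-spectrophotometric quantification of two-component mixtures,
    built around the nicotinamide/tretinoin (1:40) dermal assay.
    Provides Beer-Lambert spectral simulation from Gaussian band models,
    amplified Savitzky-Golay derivative spectra, detection of zero-crossing
    wavelengths common to an interferent family, linear calibration with
    ICH-style figures of merit (r-squared, LOD, LOQ as 3.3*sigma/S and
    10*sigma/S), mixture assay and standard-addition estimation, and a
    seeded validation battery (accuracy, precision, specificity,
    robustness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
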