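Package: oxiRaman
Title: Raman and SERS Quantification of Oxidized Nucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of 8-oxo purine nucleotides (8-oxo-dGTP in dGTP,
    8-oxo-dATP in dATP, 8-oxo-dG in dG) from Raman, low-frequency (THz) Raman
    and surface-enhanced Raman (SERS) spectra. Provides spectral I/O and
    preprocessing (polynomial baseline subtraction, phosphate-band and
    unit-vector normalization), bounded multi-Gaussian band deconvolution,
    linear marker-band calibration with contamination correction and detection
    limits, an exponential G-tetrad frequency-shift model for the THz band,
    partial least squares (NIPALS PLS1) regression for SERS spectra, and a
    synthetic-spectrum generator so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bandLibrary.R'
    'calibrate.R'
    'deconvolve.R'
    'generate.R'
    'io.R'
    'oxiRaman-package.R'
    'pls.R'
    'preprocess.R'
    'thz.R'
    'utils.R'
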