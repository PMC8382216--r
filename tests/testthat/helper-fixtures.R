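# Shared fixtures, built in code.

# A minimal spectrum directly on the fingerprint axis, flagged as
# baseline-corrected (zero baseline by construction).
fingerprintGaussian <- function(center = 1000, sigma = 8, area = 1,
                                baselineCoef = NULL) {
  axis <- seq(300, 1800, by = 0.5)
  y <- area / (sigma * sqrt(2 * pi)) * exp(-(axis - center)^2 / (2 * sigma^2))
  if (!is.null(baselineCoef)) {
    u <- axis / 1000
    for (k in seq_along(baselineCoef)) y <- y + baselineCoef[k] * u^(k - 1)
  }
  RamanSpectrum(axis, y, region = "fingerprint", species = "synthetic",
                baselineCorrected = is.null(baselineCoef))
}

thzGaussian <- function(center = 80, sigma = 25, area = 1) {
  axis <- seq(10, 200, by = 0.25)
  y <- area / (sigma * sqrt(2 * pi)) * exp(-(axis - center)^2 / (2 * sigma^2))
  RamanSpectrum(axis, y, region = "thz", species = "synthetic",
                baselineCorrected = TRUE)
}

# Pre-normalized SERS-like spectra whose response is exactly linear in one
# spectral direction: x_i = base + (y_i / 100) * direction, unit-norm flag
# set so fitPLS/predictPLS use them as-is.
linearSersSet <- function(y = seq(0, 100, by = 10)) {
  grid <- seq(400, 1800, by = 1)
  base <- exp(-(grid - 900)^2 / (2 * 120^2))
  dirn <- exp(-(grid - 1500)^2 / (2 * 60^2))
  lapply(y, function(yi)
    RamanSpectrum(grid, base + (yi / 100) * dirn, region = "sers",
                  species = "synthetic", fraction = yi,
                  baselineCorrected = TRUE, normalization = "unit-vector"))
}

expect_sigdigits <- function(actual, expected, digits) {
  expect_lt(abs(actual - expected), abs(expected) * 10^(-digits + 1) / 2)
}
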