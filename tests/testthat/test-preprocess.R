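test_that("a polynomial baseline is annihilated exactly", {
  axis <- seq(300, 1800, by = 0.5)
  u <- axis / 1000
  y <- 0.3 - 0.1 * u + 0.05 * u^2 - 0.01 * u^3
  sp <- RamanSpectrum(axis, y, region = "fingerprint")
  out <- subtractBaseline(sp, "polynomial", degree = 3,
                          anchorWindows = list(c(300, 1800)))
  expect_lt(max(abs(intensities(out))), 1e-10)
  expect_true(spectrumInfo(out)$baselineCorrected)

  # the zero spectrum stays zero
  z <- RamanSpectrum(axis, rep(0, length(axis)), region = "fingerprint")
  expect_equal(intensities(subtractBaseline(z, degree = 3,
                                            anchorWindows = list(c(300, 1800)))),
               rep(0, length(axis)))
})

test_that("band area survives linear-baseline subtraction to within 0.5%", {
  sp <- fingerprintGaussian(center = 1000, sigma = 8, area = 1,
                            baselineCoef = c(0.2, 0.15))
  out <- subtractBaseline(sp, "linear",
                          anchorWindows = list(c(300, 950), c(1050, 1800)))
  w <- wavenumbers(out)
  idx <- w >= 950 & w <= 1050
  area <- sum(diff(w[idx]) * (intensities(out)[idx][-1] +
                              intensities(out)[idx][-sum(idx)]) / 2)
  expect_lt(abs(area - 1), 0.005)
})

test_that("baseline subtraction absorbs any added baseline in its family", {
  sp <- fingerprintGaussian(center = 1100, sigma = 8, area = 1)
  anchors <- list(c(300, 1050), c(1150, 1800))
  ref <- subtractBaseline(sp, degree = 3, anchorWindows = anchors)
  shifted <- RamanSpectrum(wavenumbers(sp),
                           intensities(sp) + 0.1 + 2e-4 * wavenumbers(sp),
                           region = "fingerprint")
  out <- subtractBaseline(shifted, degree = 3, anchorWindows = anchors)
  expect_equal(intensities(out), intensities(ref), tolerance = 1e-8)
})

test_that("reference normalization is scale-invariant and idempotent", {
  sp <- generatePureSpectrum("dGTP", noiseSD = 0, baseline = NULL)
  n1 <- normalizeToReference(sp)
  scaled <- RamanSpectrum(wavenumbers(sp), 7.3 * intensities(sp),
                          region = "fingerprint", baselineCorrected = TRUE)
  n2 <- normalizeToReference(scaled)
  expect_equal(intensities(n1), intensities(n2), tolerance = 1e-12)
  expect_equal(normalizationFactor(n2) / normalizationFactor(n1), 7.3)
  # applying it twice: second factor is 1
  n3 <- normalizeToReference(n1)
  expect_equal(normalizationFactor(n3), 1, tolerance = 1e-12)
  expect_equal(intensities(n3), intensities(n1), tolerance = 1e-12)
})

test_that("normalized band areas equal the library area ratios", {
  sp <- normalizeToReference(generatePureSpectrum("dGTP", noiseSD = 0,
                                                  baseline = NULL))
  w <- wavenumbers(sp)
  idx <- w >= 1470 & w <= 1500
  area <- sum(diff(w[idx]) * (intensities(sp)[idx][-1] +
                              intensities(sp)[idx][-sum(idx)]) / 2)
  # expected: library area 0.85 times the +/-15 cm-1 window coverage of a
  # sigma = 8 Gaussian; the phosphate divisor is 1 by library construction
  expect_equal(area, 0.85 * (2 * pnorm(15 / 8) - 1), tolerance = 1e-3)
})

test_that("unit-vector normalization has norm 1 and removes the gain", {
  sp <- generateSersDataset(fractions = 40, seed = 9)$spectra[[1]]
  n1 <- unitVectorNormalize(sp)
  expect_equal(sqrt(sum(intensities(n1)^2)), 1, tolerance = 1e-12)
  expect_equal(range(wavenumbers(n1)), c(400, 1800))
  # homogeneity
  scaled <- RamanSpectrum(wavenumbers(sp), 3.1 * intensities(sp),
                          region = "sers")
  expect_equal(intensities(unitVectorNormalize(scaled)), intensities(n1),
               tolerance = 1e-12)
  # replicates at equal C with different gains agree after normalization
  reps <- generateSersDataset(fractions = c(40, 40), enhancementCV = 0.5,
                              noiseSD = 0, seed = 10)$spectra
  expect_equal(intensities(unitVectorNormalize(reps[[1]])),
               intensities(unitVectorNormalize(reps[[2]])), tolerance = 1e-10)
  # degenerate input
  flat <- RamanSpectrum(seq(115, 3200, 1), rep(0, length(seq(115, 3200, 1))),
                        region = "sers")
  expect_error(unitVectorNormalize(flat), "all-zero")
})

test_that("preprocessing preconditions are enforced", {
  raw <- generatePureSpectrum("dGTP", noiseSD = 0)   # has a baseline
  expect_error(normalizeToReference(raw), "baseline-corrected")
  sp <- fingerprintGaussian()
  expect_error(subtractBaseline(sp, degree = 5,
                                anchorWindows = list(c(300, 301))),
               "anchor points")
  expect_error(subtractBaseline(sp, degree = -1), ">= 0")
})
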