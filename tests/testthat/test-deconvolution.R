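test_that("a noiseless in-family Gaussian is recovered to solver precision", {
  sp <- fingerprintGaussian(center = 1520, sigma = 9, area = 0.7)
  init <- data.frame(center = 1520, width = 9, area = 0.7)
  res <- fitGaussians(sp, init, c(1400, 1650))
  b <- fittedBands(res)
  expect_sigdigits(b$center, 1520, 6)
  expect_sigdigits(b$width, 9, 6)
  expect_sigdigits(b$area, 0.7, 6)
  expect_lt(residualRMS(res), 1e-10)
  expect_true(converged(res))
})

test_that("the six-Gaussian protocol recovers all mixture band centers", {
  man <- generateMixtureSeries(fractions = 16, replicates = 1, noiseSD = 0,
                               baseline = NULL, seed = 1)
  sp <- normalizeToReference(readSpectrum(man$path[1]))
  init <- initBandsForWindow(defaultBandLibrary(), c("dGTP", "8-oxo-dGTP"),
                             c(1400, 1650))
  expect_equal(nrow(init), 6L)   # five assigned bands + free remnant
  res <- fitGaussians(sp, init, c(1400, 1650))
  b <- fittedBands(res)
  truth <- c(1445, 1485, 1535, 1575, 1607)
  for (ctr in truth)
    expect_lt(min(abs(b$center - ctr)), 0.5)
  expect_true(converged(res))
})

test_that("noisy deconvolution stays within 2 cm-1 / 5% of truth", {
  man <- generateMixtureSeries(fractions = 16, replicates = 1, noiseSD = 0.01,
                               seed = 42)
  sp <- readSpectrum(man$path[1])
  lib <- defaultBandLibrary()
  bandWins <- lapply(seq_len(nrow(lib$dGTP)), function(j)
    c(lib$dGTP$center[j] - 28, lib$dGTP$center[j] + 28))
  oxo <- lib[["8-oxo-dGTP"]]
  bandWins <- c(bandWins, lapply(seq_len(nrow(oxo)), function(j)
    c(oxo$center[j] - 28, oxo$center[j] + 28)))
  anchors <- oxiRaman:::intervalComplement(bandWins, 300, 1800)
  sp <- normalizeToReference(subtractBaseline(sp, degree = 3,
                                              anchorWindows = anchors))
  res <- fitGaussians(sp, initBandsForWindow(lib, c("dGTP", "8-oxo-dGTP"),
                                             c(1400, 1650)), c(1400, 1650))
  a1535 <- bandArea(res, 1535, excludeAssignments = "background remnant")
  a1607 <- bandArea(res, 1607, excludeAssignments = "background remnant")
  expect_lt(abs(a1535$center - 1535), 2)
  expect_lt(abs(a1607$center - 1607), 2)
  # areas agree with truth within their own fitted uncertainty (the broad
  # remnant component trades some area with the markers under noise)
  expect_lt(abs(a1535$area - 0.8 * 0.16), 3 * a1535$se)
  expect_lt(abs(a1607$area - 0.9 * 0.16), 3 * a1607$se)
  expect_lt(abs(a1535$area - 0.8 * 0.16) / (0.8 * 0.16), 0.10)
  expect_lt(abs(a1607$area - 0.9 * 0.16) / (0.9 * 0.16), 0.10)
})

test_that("band matching refuses absent or ambiguous targets", {
  spG <- generatePureSpectrum("dGTP", noiseSD = 0, baseline = NULL)
  init <- initBandsForWindow(defaultBandLibrary(), "dGTP", c(1400, 1650),
                             addRemnant = FALSE)
  res <- fitGaussians(spG, init, c(1400, 1650))
  expect_error(bandArea(res, 1535), "0 band")
  # two bands deliberately initialized 4 cm-1 apart near 1535
  spB <- fingerprintGaussian(center = 1535, sigma = 8, area = 0.8)
  res2 <- fitGaussians(spB, data.frame(center = c(1533, 1537),
                                       width = c(8, 8), area = c(0.4, 0.4)),
                       c(1400, 1650))
  expect_error(bandArea(res2, 1535), "2 band")
})

test_that("fitting never worsens the initialization residual", {
  man <- generateMixtureSeries(fractions = 8, replicates = 1, noiseSD = 0.02,
                               baseline = NULL, seed = 7)
  sp <- normalizeToReference(readSpectrum(man$path[1]))
  init <- initBandsForWindow(defaultBandLibrary(), c("dGTP", "8-oxo-dGTP"),
                             c(1400, 1650))
  w <- wavenumbers(sp)
  idx <- w >= 1400 & w <= 1650
  p0 <- as.numeric(t(as.matrix(init[, c("center", "width", "area")])))
  rmsInit <- sqrt(mean((oxiRaman:::gaussianSum(w[idx], p0) -
                        intensities(sp)[idx])^2))
  res <- fitGaussians(sp, init, c(1400, 1650))
  expect_lte(residualRMS(res), rmsInit)
})

test_that("area standard errors shrink roughly as 1/sqrt(replicates)", {
  getSE <- function(nrep, seed) {
    man <- generateMixtureSeries(fractions = 8, replicates = nrep,
                                 noiseSD = 0.02, baseline = NULL, seed = seed)
    sps <- lapply(man$path, readSpectrum)
    avg <- Reduce(`+`, lapply(sps, intensities)) / nrep
    sp <- normalizeToReference(RamanSpectrum(wavenumbers(sps[[1]]), avg,
                                             region = "fingerprint",
                                             baselineCorrected = TRUE))
    res <- fitGaussians(sp, initBandsForWindow(defaultBandLibrary(),
                                               c("dGTP", "8-oxo-dGTP"),
                                               c(1400, 1650)), c(1400, 1650))
    bandArea(res, 1535, excludeAssignments = "background remnant")$se
  }
  ratios <- vapply(1:3, function(s) getSE(4, s) / getSE(1, s + 10), numeric(1))
  expect_lt(mean(ratios), 0.75)   # ideal 0.5
  expect_gt(mean(ratios), 0.25)
})

test_that("the THz main band is located exactly on noiseless data", {
  mb <- thzMainBand(thzGaussian(center = 80))
  expect_lt(abs(mb$center - 80), 0.1)

  # pure species contrast exceeds 30 cm-1
  thz <- generateThzSeries(fractions = c(0, 100))
  centers <- vapply(thz$spectra, function(s) thzMainBand(s)$center, numeric(1))
  expect_gte(abs(diff(centers)), 30)

  # noise moves the extracted center by < 2 cm-1
  noisy <- generateThzSeries(fractions = 4, noiseSD = 0.02, seed = 42)
  clean <- generateThzSeries(fractions = 4, noiseSD = 0)
  expect_lt(abs(thzMainBand(noisy$spectra[[1]])$center -
                thzMainBand(clean$spectra[[1]])$center), 2)
})

test_that("window coverage and parameter-count preconditions hold", {
  sp <- fingerprintGaussian()
  expect_error(fitGaussians(sp, data.frame(center = 2000, width = 8, area = 1),
                            c(1900, 2100)), "cover")
  short <- RamanSpectrum(seq(10, 20, 1), rep(1, 11), region = "thz")
  expect_error(fitGaussians(short, data.frame(center = c(12, 14, 16, 18),
                                              width = rep(2, 4),
                                              area = rep(1, 4)),
                            c(10, 20)), "underdetermined")
})
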