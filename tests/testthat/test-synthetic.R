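test_that("a single noiseless band is an exact Gaussian at its center", {
  lib <- list(X = data.frame(center = 1000, width = 8, area = 2,
                             assignment = "test", region = "fingerprint"))
  sp <- generatePureSpectrum("X", lib, noiseSD = 0, baseline = NULL)
  w <- wavenumbers(sp)
  expect_equal(intensities(sp),
               2 / (8 * sqrt(2 * pi)) * exp(-(w - 1000)^2 / 128))
  expect_equal(w[which.max(intensities(sp))], 1000)
})

test_that("8-oxo-dGTP defaults show the three oxidation bands", {
  sp <- generatePureSpectrum("8-oxo-dGTP", noiseSD = 0, baseline = NULL)
  w <- wavenumbers(sp); y <- intensities(sp)
  for (ctr in c(1445, 1535, 1607)) {
    idx <- which(w >= ctr - 10 & w <= ctr + 10)
    expect_lte(abs(w[idx][which.max(y[idx])] - ctr), 0.5)
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- generatePureSpectrum("dGTP", noiseSD = 0.02, seed = 5)
  b <- generatePureSpectrum("dGTP", noiseSD = 0.02, seed = 5)
  expect_identical(intensities(a), intensities(b))
  # different seeds differ only in noise: difference has near-zero mean
  c <- generatePureSpectrum("dGTP", noiseSD = 0.02, seed = 6)
  d <- intensities(a) - intensities(c)
  sdNoise <- 0.02 * max(intensities(generatePureSpectrum("dGTP", noiseSD = 0,
                                                         baseline = NULL)))
  expect_lt(abs(mean(d)), 4 * sdNoise * sqrt(2 / length(d)))
})

test_that("mixtures interpolate linearly between the pure endpoints", {
  lib <- defaultBandLibrary()
  axis <- seq(300, 1800, 0.5)
  endA <- generateMixtureSeries(fractions = 0, replicates = 1, noiseSD = 0,
                                baseline = NULL, seed = 1)
  endB <- generateMixtureSeries(fractions = 100, replicates = 1, noiseSD = 0,
                                baseline = NULL, seed = 1)
  pureA <- generatePureSpectrum("dGTP", lib, noiseSD = 0, baseline = NULL)
  pureB <- generatePureSpectrum("8-oxo-dGTP", lib, noiseSD = 0, baseline = NULL)
  expect_equal(intensities(readSpectrum(endA$path[1])), intensities(pureA),
               tolerance = 1e-6)
  expect_equal(intensities(readSpectrum(endB$path[1])), intensities(pureB),
               tolerance = 1e-6)

  # noiseless marker intensity is exactly affine in C
  fr <- c(0, 4, 8, 16)
  man <- generateMixtureSeries(fractions = fr, replicates = 1, noiseSD = 0,
                               baseline = NULL, seed = 1)
  peak <- vapply(man$path, function(p) {
    sp <- readSpectrum(p)
    intensities(sp)[which(wavenumbers(sp) == 1535)]
  }, numeric(1))
  fit <- lm(peak ~ fr)
  expect_gt(summary(fit)$r.squared, 1 - 1e-10)
})

test_that("the default mixture grid yields 18 files plus a manifest", {
  man <- generateMixtureSeries(noiseSD = 0.01, seed = 3)
  expect_equal(nrow(man), 18L)
  expect_setequal(unique(man$fraction_pct), c(0, 1, 2, 4, 8, 16))
  expect_true(file.exists(attr(man, "manifestPath")))
})

test_that("THz series centers follow the exponential shift model", {
  model <- defaultTetradShiftModel("deoxy")
  ser <- generateThzSeries(fractions = c(0, 2, 8, 100), model = model)
  expect_equal(ser$centers[1], 95)                    # C = 0 -> nu_0
  expect_lt(abs(ser$centers[4] - 60), 1e-4)           # C = 100 -> nu_8oxo
  expect_equal(ser$centers, shiftFrequency(model, c(0, 2, 8, 100)))
  # argmax of each noiseless spectrum sits at the model center
  for (i in seq_along(ser$spectra)) {
    w <- wavenumbers(ser$spectra[[i]]); y <- intensities(ser$spectra[[i]])
    expect_lte(abs(w[which.max(y)] - ser$centers[i]), 0.25)
  }
})

test_that("SERS endpoint and colloid band behave as constructed", {
  d0 <- generateSersDataset(fractions = 0, enhancementCV = 0, noiseSD = 0,
                            baseline = NULL, seed = 1)
  sp <- d0$spectra[[1]]
  lib <- defaultBandLibrary()
  w <- wavenumbers(sp)
  expected <- numeric(length(w))
  for (s in c("dG", "colloid")) {
    b <- lib[[s]]
    for (i in seq_len(nrow(b)))
      expected <- expected + b$area[i] / (b$width[i] * sqrt(2 * pi)) *
        exp(-(w - b$center[i])^2 / (2 * b$width[i]^2))
  }
  expect_equal(intensities(sp), expected, tolerance = 1e-12)
  # colloid band near 240 cm-1 present at every fraction
  dAll <- generateSersDataset(seed = 2)
  for (sp in dAll$spectra) {
    idx <- which(wavenumbers(sp) >= 200 & wavenumbers(sp) <= 280)
    pk <- wavenumbers(sp)[idx][which.max(intensities(sp)[idx])]
    expect_lte(abs(pk - 240), 5)
  }
})

test_that("noiseless unit-normalized SERS data span two components", {
  d <- generateSersDataset(enhancementCV = 0.3, noiseSD = 0, seed = 4)
  X <- do.call(rbind, lapply(d$spectra, function(s)
    intensities(unitVectorNormalize(s))))
  sv <- svd(X)$d
  expect_lt(sv[3] / sv[1], 1e-10)
})

test_that("generator output always passes spectrum validation", {
  for (sp in list(generatePureSpectrum("dATP", seed = 1),
                  generatePureSpectrum("dGTP", region = "thz", seed = 1),
                  generateSersDataset(fractions = 50, seed = 1)$spectra[[1]]))
    expect_true(validObject(sp))
  expect_error(generatePureSpectrum("nope"), "not in library")
  expect_error(generatePureSpectrum("dGTP", axis = seq(1000, 1200, 0.5)),
               "too narrow")
  expect_error(generateSersDataset(enhancementCV = -1), ">= 0")
  expect_error(generateMixtureSeries(fractions = numeric(0)), "empty")
})
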