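# Synthetic spectra with the statistical structure the analysis assumes:
# Gaussian bands at assigned centers, linear mixing, smooth polynomial
# baselines, additive homoscedastic noise, and THz main-band centers that
# follow the exponential tetrad-shift model.

# Sum of a species' Gaussian bands over an axis, restricted to one region.
# Errors if a band (center +/- 2 sigma) is not covered by the axis.
speciesSignal <- function(species, library, axis, region) {
  if (!species %in% names(library)) stop("species not in library: ", species)
  bands <- library[[species]]
  checkBands(bands, species)
  if ("region" %in% names(bands)) bands <- bands[bands$region == region, , drop = FALSE]
  if (nrow(bands) == 0L)
    stop("no '", region, "' bands for species ", species)
  lo <- min(axis); hi <- max(axis)
  low2 <- bands$center - 2 * bands$width
  high2 <- bands$center + 2 * bands$width
  if (any(low2 < 0))
    stop("band at ", bands$center[which(low2 < 0)[1]],
         " cm-1 extends below 0 cm-1 (center - 2*sigma < 0)")
  if (any(low2 < lo - 1e-9) || any(high2 > hi + 1e-9))
    stop(sprintf("axis [%g, %g] too narrow for bands of %s (need center +/- 2*sigma)",
                 lo, hi, species))
  sig <- numeric(length(axis))
  for (i in seq_len(nrow(bands)))
    sig <- sig + gaussianProfile(axis, bands$center[i], bands$width[i], bands$area[i])
  sig
}

# Polynomial baseline evaluated on the axis; coefficients apply to (nu/1000)^k.
evalBaseline <- function(axis, coefficients) {
  if (is.null(coefficients) || length(coefficients) == 0L)
    return(numeric(length(axis)))
  u <- axis / 1000
  out <- numeric(length(axis))
  for (k in seq_along(coefficients)) out <- out + coefficients[k] * u^(k - 1)
  out
}

defaultAxis <- function(region) {
  switch(region,
    fingerprint = seq(300, 1800, by = 0.5),
    thz = seq(10, 200, by = 0.25),
    sers = seq(115, 3200, by = 1))
}

defaultBaselineCoef <- function(region) {
  switch(region,
    fingerprint = c(0.02, 0.010, -0.005, 0.002),
    thz = c(0, 0),
    sers = c(0.05, 0.02, -0.004))
}

#' Generate a pure-species synthetic spectrum
#'
#' Intensities are the sum of the species' Gaussian bands (from the band
#' library, restricted to `region`) plus a polynomial baseline and additive
#' iid normal noise with SD `noiseSD * max(band signal)`. Deterministic for
#' a fixed seed.
#'
#' @param species species label present in `library`.
#' @param library band library, see [defaultBandLibrary()].
#' @param region `"fingerprint"`, `"thz"` or `"sers"`.
#' @param axis wavenumber grid (cm^-1); default per region (fingerprint
#'   300--1800 at 0.5, THz 10--200 at 0.25, SERS 115--3200 at 1).
#' @param baseline polynomial coefficients for `(nu/1000)^k`; `NULL` for a
#'   zero baseline, `"default"` for the region default.
#' @param noiseSD noise SD as a fraction of the maximum band-signal
#'   intensity.
#' @param seed integer RNG seed (ignored when `noiseSD = 0`).
#' @return A [RamanSpectrum-class].
#' @examples
#' sp <- generatePureSpectrum("8-oxo-dGTP", noiseSD = 0, baseline = NULL)
#' wavenumbers(sp)[which.max(intensities(sp))]  # phosphate band, 1123 cm-1
#' @export
generatePureSpectrum <- function(species, library = defaultBandLibrary(),
                                 region = "fingerprint", axis = NULL,
                                 baseline = "default", noiseSD = 0.01,
                                 seed = NULL) {
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  axis <- axis %||% defaultAxis(region)
  if (identical(baseline, "default")) baseline <- defaultBaselineCoef(region)
  sig <- speciesSignal(species, library, axis, region)
  y <- sig + evalBaseline(axis, baseline)
  if (noiseSD > 0)
    y <- y + withSeed(seed, stats::rnorm(length(axis), 0, noiseSD * max(sig)))
  RamanSpectrum(axis, y, region = region, species = species,
                fraction = if (grepl("^8-oxo", species)) 100 else 0,
                baselineCorrected = is.null(baseline) || all(baseline == 0))
}

#' Generate a two-species mixture series and its manifest
#'
#' For each fraction C (percent) and replicate, the spectrum is
#' `(1 - C'/100) * signal_A + (C'/100) * signal_B + baseline + noise` with
#' `C' = C + c0Pct`, where `c0Pct` simulates accidental contamination of the
#' nominally pure non-oxidized sample. Marker-band areas are exactly linear
#' in C before noise. Files and a manifest CSV are written to `outDir`.
#'
#' @param fractions percent values of species B; default 0--16% as used for
#'   8-oxo-dGTP/dGTP mixtures.
#' @param replicates spectra per fraction.
#' @param speciesA,speciesB the non-oxidized and oxidized species.
#' @param library band library.
#' @param region spectral region (default `"fingerprint"`).
#' @param axis wavenumber grid; region default when `NULL`.
#' @param baseline polynomial baseline coefficients (`"default"` = region
#'   default, `NULL` = none).
#' @param noiseSD noise SD as fraction of the max noiseless mixture signal.
#' @param c0Pct accidental oxidized contamination added to every mixture.
#' @param seed integer RNG seed.
#' @param outDir output directory (created if needed).
#' @return The manifest data.frame (absolute paths), invisibly carrying the
#'   manifest path in attribute `"manifestPath"`.
#' @export
generateMixtureSeries <- function(fractions = c(0, 1, 2, 4, 8, 16),
                                  replicates = 3,
                                  speciesA = "dGTP", speciesB = "8-oxo-dGTP",
                                  library = defaultBandLibrary(),
                                  region = "fingerprint", axis = NULL,
                                  baseline = "default", noiseSD = 0.01,
                                  c0Pct = 0, seed = NULL,
                                  outDir = tempfile("mixtures")) {
  if (length(fractions) == 0L) stop("empty fraction list")
  if (any(fractions < 0 | fractions > 100)) stop("fractions must be in [0, 100]")
  axis <- axis %||% defaultAxis(region)
  if (identical(baseline, "default")) baseline <- defaultBaselineCoef(region)
  sigA <- speciesSignal(speciesA, library, axis, region)
  sigB <- speciesSignal(speciesB, library, axis, region)
  base <- evalBaseline(axis, baseline)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  withSeed(seed, {
    for (C in fractions) for (r in seq_len(replicates)) {
      Ceff <- min(C + c0Pct, 100)
      sig <- (1 - Ceff / 100) * sigA + (Ceff / 100) * sigB
      y <- sig + base
      if (noiseSD > 0) y <- y + stats::rnorm(length(axis), 0, noiseSD * max(sig))
      sp <- RamanSpectrum(axis, y, region = region, species = "mixture",
                          fraction = C,
                          baselineCorrected = is.null(baseline) ||
                            all(baseline == 0))
      fn <- file.path(outDir, sprintf("mixture_C%g_r%d.txt", C, r))
      writeSpectrum(sp, fn)
      rows[[length(rows) + 1L]] <- data.frame(
        path = fn, species = "mixture", fraction_pct = C, replicate = r,
        stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(outDir, "manifest.csv")
  writeManifest(manifest, mpath)
  attr(manifest, "manifestPath") <- mpath
  manifest
}

#' Generate a THz mixture series following the tetrad-shift model
#'
#' Each spectrum holds one dominant broad Gaussian whose center is
#' `nu(C) = nu_8oxo + (nu_0 - nu_8oxo) exp(-C/R)` from the supplied model,
#' on a 10--200 cm^-1 axis, plus an optional linear baseline and noise.
#'
#' @param fractions percent values.
#' @param model a [TetradShiftModel-class]; deoxy default.
#' @param bandWidth Gaussian sigma of the broad band (cm^-1).
#' @param bandArea band area (arbitrary units).
#' @param noiseSD noise SD as fraction of max signal.
#' @param baseline linear baseline coefficients (`NULL` = none).
#' @param seed integer RNG seed.
#' @param outDir optional output directory; when given, files plus a
#'   manifest are written as in [generateMixtureSeries()].
#' @return list with `spectra` (list of [RamanSpectrum-class]), `fractions`,
#'   `centers` (the true band centers) and, when written, `manifest`.
#' @export
generateThzSeries <- function(fractions = c(0, 1, 2, 4, 8, 16),
                              model = defaultTetradShiftModel("deoxy"),
                              bandWidth = 25, bandArea = 1,
                              noiseSD = 0, baseline = NULL, seed = NULL,
                              outDir = NULL) {
  stopifnot(is(model, "TetradShiftModel"))
  if (length(fractions) == 0L) stop("empty fraction list")
  axis <- defaultAxis("thz")
  centers <- shiftFrequency(model, fractions)
  if (any(centers - 2 * bandWidth < 0))
    stop("THz band extends below 0 cm-1 (center - 2*sigma < 0)")
  if (any(centers - 2 * bandWidth < min(axis) - 1e-9) ||
      any(centers + 2 * bandWidth > max(axis) + 1e-9))
    stop("THz axis too narrow for band centers +/- 2*sigma")
  base <- evalBaseline(axis, baseline)
  spectra <- vector("list", length(fractions))
  rows <- list()
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  withSeed(seed, {
    for (i in seq_along(fractions)) {
      sig <- gaussianProfile(axis, centers[i], bandWidth, bandArea)
      y <- sig + base
      if (noiseSD > 0) y <- y + stats::rnorm(length(axis), 0, noiseSD * max(sig))
      sp <- RamanSpectrum(axis, y, region = "thz", species = "mixture",
                          fraction = fractions[i],
                          baselineCorrected = is.null(baseline) ||
                            all(baseline == 0))
      spectra[[i]] <- sp
      if (!is.null(outDir)) {
        fn <- file.path(outDir, sprintf("thz_C%g.txt", fractions[i]))
        writeSpectrum(sp, fn)
        rows[[length(rows) + 1L]] <- data.frame(
          path = fn, species = "mixture", fraction_pct = fractions[i],
          replicate = 1L, stringsAsFactors = FALSE)
      }
    }
  })
  out <- list(spectra = spectra, fractions = fractions, centers = centers)
  if (!is.null(outDir)) {
    manifest <- do.call(rbind, rows)
    writeManifest(manifest, file.path(outDir, "manifest.csv"))
    out$manifest <- manifest
  }
  out
}

#' Generate a SERS nucleoside mixture dataset
#'
#' Each spectrum is `g * [(1 - C/100) * dG + (C/100) * 8-oxo-dG + colloid +
#' baseline] + noise`, with per-spectrum gain `g ~ lognormal(0,
#' enhancementCV)` modeling SERS enhancement and collection-efficiency
#' variability. The gain multiplies the whole measured emission (analyte,
#' colloid band and background alike), which is what makes unit-vector
#' normalization remove it; additive detector noise is applied after the
#' gain. The axis covers 115--3200 cm^-1; analysis later restricts to
#' 400--1800 cm^-1, which excludes the colloid band near 240 cm^-1.
#'
#' @param fractions percent values over 0--100.
#' @param library band library (must contain `dG`, `8-oxo-dG`, `colloid`).
#' @param enhancementCV sdlog of the lognormal gain (>= 0).
#' @param noiseSD noise SD as fraction of max pure signal.
#' @param baseline polynomial baseline coefficients (`"default"` = broad
#'   SERS background).
#' @param seed integer RNG seed.
#' @return list with `spectra` (list of [RamanSpectrum-class]) and
#'   `fractions`.
#' @export
generateSersDataset <- function(fractions = seq(0, 100, by = 10),
                                library = defaultBandLibrary(),
                                enhancementCV = 0.2, noiseSD = 0.01,
                                baseline = "default", seed = NULL) {
  if (enhancementCV < 0) stop("enhancementCV must be >= 0")
  if (any(fractions < 0 | fractions > 100)) stop("fractions must be in [0, 100]")
  axis <- defaultAxis("sers")
  if (identical(baseline, "default")) baseline <- defaultBaselineCoef("sers")
  sigA <- speciesSignal("dG", library, axis, "sers")
  sigB <- speciesSignal("8-oxo-dG", library, axis, "sers")
  colloid <- speciesSignal("colloid", library, axis, "sers")
  base <- evalBaseline(axis, baseline)
  spectra <- vector("list", length(fractions))
  withSeed(seed, {
    for (i in seq_along(fractions)) {
      C <- fractions[i]
      mix <- (1 - C / 100) * sigA + (C / 100) * sigB
      g <- if (enhancementCV > 0) stats::rlnorm(1, 0, enhancementCV) else 1
      y <- g * (mix + colloid + base)
      if (noiseSD > 0) y <- y + stats::rnorm(length(axis), 0, noiseSD * max(mix))
      spectra[[i]] <- RamanSpectrum(axis, y, region = "sers",
                                    species = "mixture", fraction = C)
    }
  })
  list(spectra = spectra, fractions = fractions)
}
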