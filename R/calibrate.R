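# Linear marker-band calibration: I = m * C + I0, with optional
# contamination (C0) correction and inverse prediction with propagated
# uncertainty.

#' Build a marker-band calibration curve
#'
#' Ordinary (or, when per-point errors are supplied, 1/err^2-weighted)
#' least-squares line through (C, I) points, where I is a normalized
#' marker-band area and C the oxidized fraction in percent. With
#' `correctC0 = TRUE`, the fitted intensity at C = 0 — interpreted as an
#' accidental oxidized contamination of the nominally pure sample — is
#' subtracted from all points and the line refit through the origin, so the
#' reported intercept is 0 by construction.
#'
#' @param points data.frame with columns `C` (percent), `area` and
#'   optionally `err` (area standard errors).
#' @param correctC0 apply the contamination correction?
#' @param band label for the curve (e.g. `"1535"`).
#' @return A [CalibrationCurve-class].
#' @examples
#' pts <- data.frame(C = c(0, 1, 2, 4, 8, 16), area = 0.008 * c(0, 1, 2, 4, 8, 16))
#' buildCalibration(pts, band = "1535")
#' @export
buildCalibration <- function(points, correctC0 = TRUE, band = "band") {
  stopifnot(all(c("C", "area") %in% names(points)))
  C <- points$C; I <- points$area
  if (length(unique(C)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (stats::sd(C) == 0) stop("degenerate design: no concentration spread")
  wts <- if ("err" %in% names(points) && all(is.finite(points$err)) &&
             all(points$err > 0)) 1 / points$err^2 else NULL
  fit <- stats::lm(I ~ C, weights = wts)
  sm <- suppressWarnings(summary(fit))  # noiseless synthetic data fit exactly
  intercept <- stats::coef(fit)[[1]]
  interceptSE <- sm$coefficients[1, 2]
  if (correctC0) {
    I0 <- I - intercept
    fit0 <- stats::lm(I0 ~ C - 1, weights = wts)
    slope <- stats::coef(fit0)[[1]]
    # the slope SE must account for the estimated intercept: take it from
    # the two-parameter fit (the through-origin refit would understate it)
    slopeSE <- sm$coefficients[2, 2]
    resid <- stats::residuals(fit0)
    dof <- max(length(C) - 2L, 1L)
    new("CalibrationCurve", band = band, slope = slope, slopeSE = slopeSE,
        intercept = 0, interceptSE = interceptSE,
        sigmaRes = sqrt(sum(resid^2) / dof),
        concRange = range(C), n = length(C), c0Corrected = TRUE)
  } else {
    slope <- stats::coef(fit)[[2]]
    slopeSE <- sm$coefficients[2, 2]
    resid <- stats::residuals(fit)
    dof <- max(length(C) - 2L, 1L)
    new("CalibrationCurve", band = band, slope = slope, slopeSE = slopeSE,
        intercept = intercept, interceptSE = interceptSE,
        sigmaRes = sqrt(sum(resid^2) / dof),
        concRange = range(C), n = length(C), c0Corrected = FALSE)
  }
}

#' Average two calibration curves
#'
#' Inverse-variance-weighted mean of the slopes of two curves built on the
#' same concentration design (both contamination-corrected), as used to
#' combine the 1535 and 1607 cm^-1 markers into a single calibration.
#'
#' @param curveA,curveB [CalibrationCurve-class] objects.
#' @return The averaged [CalibrationCurve-class] (band `"averaged"`).
#' @export
averageCalibration <- function(curveA, curveB) {
  stopifnot(is(curveA, "CalibrationCurve"), is(curveB, "CalibrationCurve"))
  if (!isTRUE(all.equal(curveA@concRange, curveB@concRange)) ||
      curveA@n != curveB@n)
    stop("curves were built on different concentration designs")
  if (!curveA@c0Corrected || !curveB@c0Corrected)
    stop("both curves must be contamination-corrected before averaging")
  wA <- 1 / curveA@slopeSE^2; wB <- 1 / curveB@slopeSE^2
  slope <- (wA * curveA@slope + wB * curveB@slope) / (wA + wB)
  slopeSE <- sqrt(1 / (wA + wB))
  sigmaRes <- sqrt((curveA@sigmaRes^2 + curveB@sigmaRes^2) / 2)
  new("CalibrationCurve", band = "averaged", slope = slope, slopeSE = slopeSE,
      intercept = 0, interceptSE = 0, sigmaRes = sigmaRes,
      concRange = curveA@concRange, n = curveA@n, c0Corrected = TRUE)
}

#' Invert a calibration curve
#'
#' `C = (I - I0) / m`, with standard uncertainty from first-order
#' propagation of the area error, the slope error and the calibration
#' residual scatter. Estimates below 0% are reported with the `belowRange`
#' flag, never clipped — truncation would bias validation statistics.
#'
#' @param curve a [CalibrationCurve-class] with nonzero slope.
#' @param area measured normalized band area.
#' @param areaErr its standard error (0 when unknown).
#' @return A [ConcentrationEstimate-class].
#' @examples
#' crv <- buildCalibration(
#'   data.frame(C = c(0, 1, 2, 4, 8, 16), area = 0.008 * c(0, 1, 2, 4, 8, 16)))
#' predictConcentration(crv, 0.064)  # C = 8%
#' @export
predictConcentration <- function(curve, area, areaErr = 0) {
  stopifnot(is(curve, "CalibrationCurve"))
  m <- curve@slope
  if (m == 0) stop("zero slope: calibration cannot be inverted")
  C <- (area - curve@intercept) / m
  u <- sqrt((areaErr^2 + curve@sigmaRes^2) / m^2 + (C * curve@slopeSE / m)^2)
  new("ConcentrationEstimate", value = C, uncertainty = u,
      curve = curve@band, belowRange = C < 0)
}

#' Detection limit of a calibration curve
#'
#' `LOD = k * sigma_res / m` with the ICH-style multiplier k = 3.3 by
#' default. The criterion multiplier is configurable; no universal
#' definition exists for spectroscopic band-area calibrations.
#'
#' @param curve a [CalibrationCurve-class] with positive slope.
#' @param k multiplier (default 3.3).
#' @return LOD in percent oxidized fraction.
#' @export
detectionLimit <- function(curve, k = 3.3) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (curve@slope <= 0) stop("detection limit requires a positive slope")
  k * curve@sigmaRes / curve@slope
}

#' Full fingerprint quantification pipeline for a mixture series
#'
#' For every spectrum in the manifest: read, polynomial baseline
#' subtraction (degree 3, anchors = the complement of all library band
#' regions), phosphate-band normalization, bounded multi-Gaussian
#' deconvolution of `window` initialized from the band library (plus the
#' free mid-window remnant for the (d)GTP protocol), and extraction of each
#' marker-band area. A contamination-corrected calibration curve is then
#' built per marker.
#'
#' @param manifest data.frame from [loadManifest()] or
#'   [generateMixtureSeries()].
#' @param markers marker-band centers, cm^-1 (default `c(1535, 1607)`).
#' @param species species pair whose library bands initialize the fit.
#' @param library band library.
#' @param window deconvolution interval (default `c(1400, 1650)`).
#' @param refCenter,refHalfWindow reference-band normalization parameters.
#' @param polyDegree baseline polynomial degree.
#' @param addRemnant include the free mid-window component (the sixth
#'   Gaussian of the (d)GTP protocol)?
#' @param correctC0 apply the contamination correction.
#' @return list with `curves` (named list of [CalibrationCurve-class]) and
#'   `points` (the per-spectrum marker areas).
#' @export
markerCalibration <- function(manifest, markers = c(1535, 1607),
                              species = c("dGTP", "8-oxo-dGTP"),
                              library = defaultBandLibrary(),
                              window = c(1400, 1650),
                              refCenter = 1123, refHalfWindow = 15,
                              polyDegree = 3, addRemnant = TRUE,
                              correctC0 = TRUE) {
  init <- initBandsForWindow(library, species, window,
                             addRemnant = addRemnant)
  # signal-free anchor windows: complement of all band regions of the pair
  allBands <- do.call(rbind, lapply(species, function(s) {
    b <- library[[s]]
    b[b$region == "fingerprint", c("center", "width")]
  }))
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    sp <- readSpectrum(manifest$path[i])
    bandWins <- lapply(seq_len(nrow(allBands)), function(j)
      c(allBands$center[j] - 3.5 * allBands$width[j],
        allBands$center[j] + 3.5 * allBands$width[j]))
    anchors <- intervalComplement(bandWins, wavenumbers(sp)[1],
                                  wavenumbers(sp)[length(sp)])
    sp <- subtractBaseline(sp, "polynomial", degree = polyDegree,
                           anchorWindows = anchors)
    sp <- normalizeToReference(sp, refCenter, refHalfWindow)
    fit <- fitGaussians(sp, init, window)
    b <- fittedBands(fit)
    for (mk in markers) {
      # identity by initialized component: a marker band with (near-)zero
      # area in low-C mixtures has an unidentifiable center, so matching
      # the fitted center against the target would fail spuriously there
      j <- which(init$center == mk)
      if (length(j) != 1L)
        stop("marker ", mk, " is not a unique initialized band")
      rows[[length(rows) + 1L]] <- data.frame(
        C = manifest$fraction_pct[i], marker = mk,
        area = b$area[j], err = b$areaSE[j], stringsAsFactors = FALSE)
    }
  }
  pts <- do.call(rbind, rows)
  curves <- lapply(markers, function(mk) {
    p <- pts[pts$marker == mk, c("C", "area", "err")]
    buildCalibration(p, correctC0 = correctC0, band = as.character(mk))
  })
  names(curves) <- as.character(markers)
  list(curves = curves, points = pts)
}
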