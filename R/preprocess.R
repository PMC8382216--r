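#' Subtract a polynomial or linear baseline
#'
#' Fits the chosen baseline by least squares to anchor points assumed
#' signal-free and subtracts it over the full axis, reproducing the usual
#' conventions: polynomial baseline in the fingerprint region, linear
#' background in the low-frequency range.
#'
#' Anchors are taken from `anchorWindows` when supplied; otherwise they are
#' auto-selected as the points whose intensity falls in the lowest decile
#' (a heuristic that works when band-free stretches exist across the axis;
#' prefer explicit windows when the band positions are known).
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param mode `"polynomial"` or `"linear"`.
#' @param degree polynomial degree (ignored for `mode = "linear"`, which is
#'   degree 1).
#' @param anchorWindows list of `c(lo, hi)` wavenumber intervals assumed
#'   signal-free; `NULL` for automatic selection.
#' @return The baseline-corrected [RamanSpectrum-class] (flagged).
#' @examples
#' sp <- generatePureSpectrum("dGTP", noiseSD = 0, seed = 1)
#' corr <- subtractBaseline(sp, degree = 3)
#' spectrumInfo(corr)$baselineCorrected
#' @export
subtractBaseline <- function(spectrum, mode = c("polynomial", "linear"),
                             degree = 3, anchorWindows = NULL) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  mode <- match.arg(mode)
  if (mode == "linear") degree <- 1L
  if (degree < 0) stop("degree must be >= 0")
  w <- spectrum@wavenumber
  y <- spectrum@intensity
  if (is.null(anchorWindows)) {
    anchor <- y <= stats::quantile(y, 0.1)
  } else {
    anchor <- inWindows(w, anchorWindows)
  }
  if (sum(anchor) < degree + 1L)
    stop(sprintf("only %d anchor points for a degree-%d baseline",
                 sum(anchor), degree))
  # centered/scaled abscissa for conditioning
  u <- (w - mean(w)) / stats::sd(w)
  X <- outer(u, 0:degree, `^`)
  beta <- stats::lm.fit(X[anchor, , drop = FALSE], y[anchor])$coefficients
  beta[is.na(beta)] <- 0
  corrected <- y - drop(X %*% beta)
  meta <- spectrum@metadata
  RamanSpectrum(w, corrected, region = meta$region, species = meta$species,
                fraction = meta$fraction, baselineCorrected = TRUE,
                normalization = meta$normalization)
}

#' Normalize to the phosphate reference band
#'
#' Divides all intensities by the trapezoidally integrated area in
#' `[refCenter - halfWindow, refCenter + halfWindow]`. The default reference
#' is the phosphate-backbone stretch at 1123 cm^-1, present at constant
#' amount in all nucleotide mixtures and therefore a natural internal
#' standard. Area (not peak height) is used: it is robust to width changes.
#'
#' @param spectrum a baseline-corrected [RamanSpectrum-class].
#' @param refCenter reference band center, cm^-1 (default 1123).
#' @param halfWindow half width of the integration window, cm^-1.
#' @return The normalized spectrum; the divisor is stored in the metadata
#'   and available via [normalizationFactor()].
#' @export
normalizeToReference <- function(spectrum, refCenter = 1123, halfWindow = 15) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  m <- spectrum@metadata
  if (!isTRUE(m$baselineCorrected))
    stop("spectrum must be baseline-corrected before reference normalization")
  w <- spectrum@wavenumber
  lo <- refCenter - halfWindow; hi <- refCenter + halfWindow
  if (w[1] > lo || w[length(w)] < hi)
    stop(sprintf("axis does not cover the reference window [%g, %g]", lo, hi))
  idx <- w >= lo & w <= hi
  area <- trapz(w[idx], spectrum@intensity[idx])
  if (area <= 0) stop("non-positive reference band area: ", format(area))
  RamanSpectrum(w, spectrum@intensity / area, region = m$region,
                species = m$species, fraction = m$fraction,
                baselineCorrected = TRUE, normalization = "reference",
                extra = list(normFactor = area))
}

#' Crop and unit-vector normalize
#'
#' Crops to the closed `window` (endpoints inclusive on the grid) and
#' divides intensities by their Euclidean norm, removing multiplicative
#' enhancement variability — the standard preprocessing for SERS spectra
#' before multivariate regression, over 400--1800 cm^-1.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param window `c(lo, hi)` wavenumber interval, cm^-1.
#' @return The cropped, unit-norm spectrum (normalization flag
#'   `"unit-vector"`).
#' @export
unitVectorNormalize <- function(spectrum, window = c(400, 1800)) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  w <- spectrum@wavenumber
  if (w[1] > window[1] || w[length(w)] < window[2])
    stop(sprintf("axis does not cover the window [%g, %g]", window[1], window[2]))
  idx <- w >= window[1] & w <= window[2]
  y <- spectrum@intensity[idx]
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("all-zero window, cannot unit-normalize")
  m <- spectrum@metadata
  RamanSpectrum(w[idx], y / nrm, region = m$region, species = m$species,
                fraction = m$fraction,
                baselineCorrected = isTRUE(m$baselineCorrected),
                normalization = "unit-vector",
                extra = list(normFactor = nrm))
}
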