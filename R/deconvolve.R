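# Bounded multi-Gaussian least-squares deconvolution.
#
# Bands are parameterized by (center, sigma, area); amplitude is derived.
# Centers are bounded to +/-20 cm-1 of their initialization, widths to
# [1, 60] cm-1 and areas to >= 0. The solver is trust-region bounded
# Levenberg-Marquardt (minpack) with a 2000-evaluation cap; it is
# deterministic. Standard errors come from the local covariance
# RMS^2 * (J^T J)^-1 at the solution.

gaussianSum <- function(x, p) {
  n <- length(p) / 3L
  out <- numeric(length(x))
  for (i in seq_len(n)) {
    j <- 3L * (i - 1L)
    out <- out + gaussianProfile(x, p[j + 1L], p[j + 2L], p[j + 3L])
  }
  out
}

#' Fit a sum of bounded Gaussians to a spectral window
#'
#' The six-Gaussian protocol for the 1400--1650 cm^-1 oxidation-sensitive
#' region of (d)GTP mixtures, and every other window fit, go through this
#' routine: nonlinear least squares over (center, width, area) per band with
#' centers bounded to +/-20 cm^-1 of the initialization, widths in
#' [1, 60] cm^-1 and non-negative areas.
#'
#' @param spectrum a preprocessed [RamanSpectrum-class] covering `window`.
#' @param initBands data.frame with columns `center`, `width`, `area` (and
#'   optionally `assignment`) giving the initialization.
#' @param window `c(lo, hi)` fit interval, cm^-1.
#' @return A [DeconvolutionResult-class]; `converged(result)` is `FALSE`
#'   (not an error) when the evaluation limit was hit.
#' @examples
#' sp <- generatePureSpectrum("8-oxo-dGTP", noiseSD = 0, baseline = NULL)
#' init <- defaultBandLibrary()[["8-oxo-dGTP"]]
#' res <- fitGaussians(sp, init[init$center > 1400, ], c(1400, 1650))
#' fittedBands(res)
#' @export
fitGaussians <- function(spectrum, initBands, window) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  checkBands(initBands, "initialization")
  w <- spectrum@wavenumber
  if (w[1] > window[1] || w[length(w)] < window[2])
    stop(sprintf("axis does not cover the window [%g, %g]", window[1], window[2]))
  idx <- w >= window[1] & w <= window[2]
  x <- w[idx]; y <- spectrum@intensity[idx]
  nb <- nrow(initBands)
  nPar <- 3L * nb
  if (length(x) < nPar + 1L)
    stop(sprintf("underdetermined: %d points for %d parameters", length(x), nPar))
  p0 <- as.numeric(t(as.matrix(initBands[, c("center", "width", "area")])))
  lower <- as.numeric(rbind(initBands$center - 20, 1, 0))
  upper <- as.numeric(rbind(initBands$center + 20, 60, Inf))
  # keep initial widths inside bounds
  p0 <- pmin(pmax(p0, lower), upper)
  resFn <- function(p) gaussianSum(x, p) - y
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resFn,
    control = minpack.lm::nls.lm.control(maxfev = 2000, maxiter = 1000,
                                         ftol = 1e-10, ptol = 1e-10))
  p <- fit$par
  res <- resFn(p)
  J <- fdJacobian(resFn, p)
  covm <- covFromJacobian(J, res, nPar)
  se <- sqrt(pmax(diag(covm), 0))
  bands <- data.frame(
    center = p[seq(1, nPar, 3)], width = p[seq(2, nPar, 3)],
    area = p[seq(3, nPar, 3)],
    centerSE = se[seq(1, nPar, 3)], widthSE = se[seq(2, nPar, 3)],
    areaSE = se[seq(3, nPar, 3)],
    assignment = if ("assignment" %in% names(initBands)) initBands$assignment
                 else rep(NA_character_, nb),
    stringsAsFactors = FALSE)
  # bounded centers may sit just outside the data window; clamp for validity
  bands$center <- pmin(pmax(bands$center, window[1]), window[2])
  conv <- fit$info %in% 1:4
  new("DeconvolutionResult", window = as.numeric(window), bands = bands,
      residualRMS = sqrt(mean(res^2)), covariance = covm, converged = conv)
}

#' Extract a band's integrated area by nearest-center matching
#'
#' Identifies the fitted band whose center lies within `tol` of
#' `targetCenter`; zero or multiple matches are an ambiguity error listing
#' the candidates (no silent choice).
#'
#' @param result a [DeconvolutionResult-class].
#' @param targetCenter expected band center, cm^-1.
#' @param tol matching tolerance, cm^-1 (default 10).
#' @param excludeAssignments assignments to leave out of the matching, e.g.
#'   the free `"background remnant"` component, whose fitted center is
#'   meaningless when its area vanishes.
#' @return list with `area`, `se` and `center` of the matched band.
#' @export
bandArea <- function(result, targetCenter, tol = 10,
                     excludeAssignments = NULL) {
  stopifnot(is(result, "DeconvolutionResult"))
  b <- result@bands
  if (!is.null(excludeAssignments))
    b <- b[!(b$assignment %in% excludeAssignments), , drop = FALSE]
  d <- abs(b$center - targetCenter)
  hit <- which(d <= tol)
  if (length(hit) != 1L)
    stop(sprintf(
      "%d band(s) within %g cm-1 of %g (fitted centers: %s)",
      length(hit), tol, targetCenter,
      paste(sprintf("%.1f", b$center), collapse = ", ")))
  list(area = b$area[hit], se = b$areaSE[hit], center = b$center[hit])
}

#' Locate the main THz band
#'
#' Fits one broad Gaussian over 10--200 cm^-1 and, optionally, a second
#' component which is kept only when it reduces the residual RMS by more
#' than 20%; returns the center of the largest-area component. This is the
#' robust replacement for a raw argmax when extracting the tetrad-sensitive
#' main-band frequency.
#'
#' @param spectrum a baseline-corrected THz [RamanSpectrum-class].
#' @param window fit interval, cm^-1 (default `c(10, 200)`).
#' @return list with `center`, `se` and the kept
#'   [DeconvolutionResult-class] as `fit`.
#' @export
thzMainBand <- function(spectrum, window = c(10, 200)) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  m <- spectrum@metadata
  if (!identical(m$region, "thz")) stop("not a THz spectrum")
  if (!isTRUE(m$baselineCorrected))
    stop("spectrum must be baseline-corrected before THz band extraction")
  w <- spectrum@wavenumber
  idx <- w >= window[1] & w <= window[2]
  x <- w[idx]; y <- spectrum@intensity[idx]
  c0 <- x[which.max(y)]
  a0 <- max(trapz(x, pmax(y, 0)), .Machine$double.eps)
  init1 <- data.frame(center = c0, width = 25, area = a0)
  fit1 <- fitGaussians(spectrum, init1, window)
  if (!fit1@converged) stop("THz main-band fit did not converge")
  init2 <- rbind(init1,
                 data.frame(center = min(max(c0 + 40, window[1] + 20),
                                         window[2] - 20),
                            width = 30, area = a0 / 4))
  fit2 <- tryCatch(fitGaussians(spectrum, init2, window),
                   error = function(e) NULL)
  keep <- fit1
  if (!is.null(fit2) && fit2@converged &&
      fit2@residualRMS < 0.8 * fit1@residualRMS)
    keep <- fit2
  b <- keep@bands
  i <- which.max(b$area)
  list(center = b$center[i], se = b$centerSE[i], fit = keep)
}

#' Library-based initialization for a window fit
#'
#' Collects the fingerprint bands of one or two species that fall inside
#' `window` (deduplicated by center) and, optionally, appends one free
#' "background remnant" component initialized mid-window — the sixth
#' component of the 1400--1650 cm^-1 protocol, whose identity is left
#' unassigned.
#'
#' @param library band library.
#' @param species character vector of species labels.
#' @param window `c(lo, hi)` interval, cm^-1.
#' @param region band region to draw from (default `"fingerprint"`).
#' @param addRemnant append the free mid-window component?
#' @return data.frame of initial bands.
#' @export
initBandsForWindow <- function(library, species, window,
                               region = "fingerprint", addRemnant = TRUE) {
  rows <- list()
  for (s in species) {
    b <- library[[s]]
    if (is.null(b)) stop("species not in library: ", s)
    if ("region" %in% names(b)) b <- b[b$region == region, , drop = FALSE]
    b <- b[b$center >= window[1] & b$center <= window[2], , drop = FALSE]
    if (nrow(b)) rows[[length(rows) + 1L]] <- b
  }
  init <- do.call(rbind, rows)
  if (is.null(init) || nrow(init) == 0L)
    stop("no library bands inside the window")
  init <- init[!duplicated(init$center), , drop = FALSE]
  # start marker areas small: mixtures contain them in unknown proportion
  init$area <- pmin(init$area, 0.3)
  if (addRemnant)
    init <- rbind(init, data.frame(
      center = mean(window), width = 30, area = 0.05,
      assignment = "background remnant", region = region,
      stringsAsFactors = FALSE))
  init[order(init$center), , drop = FALSE]
}
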