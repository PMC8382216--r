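#' @import methods
NULL

.regions <- c("fingerprint", "thz", "sers")

#' RamanSpectrum: a single Raman spectrum
#'
#' The universal currency of the pipeline: a strictly increasing wavenumber
#' axis (cm^-1), intensities in arbitrary units, and provenance metadata
#' (species or "mixture", nominal oxidized fraction in percent, spectral
#' region, and processing-state flags).
#'
#' Region tags constrain axis coverage: `"thz"` spectra must reach below
#' 100 cm^-1, `"fingerprint"` spectra must cover 900--1700 cm^-1 and `"sers"`
#' spectra 400--1800 cm^-1.
#'
#' @slot wavenumber numeric, strictly increasing, cm^-1.
#' @slot intensity numeric, same length, arbitrary units.
#' @slot metadata list with elements `species`, `fraction` (percent or `NA`),
#'   `region`, `baselineCorrected`, `normalization` (`"none"`, `"reference"`
#'   or `"unit-vector"`) and optionally `normFactor`.
#'
#' @aliases RamanSpectrum-class
#' @exportClass RamanSpectrum
setClass("RamanSpectrum",
  slots = c(wavenumber = "numeric", intensity = "numeric", metadata = "list"))

setValidity("RamanSpectrum", function(object) {
  w <- object@wavenumber
  y <- object@intensity
  m <- object@metadata
  if (length(w) != length(y)) return("wavenumber and intensity lengths differ")
  if (length(w) < 2L) return("spectrum needs at least 2 points")
  if (!all(is.finite(w)) || !all(is.finite(y))) return("non-finite values")
  if (any(diff(w) <= 0)) return("wavenumbers must be strictly increasing")
  if (is.null(m$region) || !m$region %in% .regions)
    return(sprintf("region must be one of %s", paste(.regions, collapse = ", ")))
  lo <- w[1L]; hi <- w[length(w)]
  step <- stats::median(diff(w))   # coverage to within one grid step
  cov <- switch(m$region,
    thz = lo < 100,
    fingerprint = lo <= 900 + step && hi >= 1700 - step,
    sers = lo <= 400 + step && hi >= 1800 - step)
  if (!cov) return(sprintf("axis [%.6g, %.6g] does not cover the '%s' region",
                           lo, hi, m$region))
  if (!is.null(m$fraction) && !is.na(m$fraction) &&
      (m$fraction < 0 || m$fraction > 100))
    return("fraction must be in [0, 100] or NA")
  TRUE
})

#' Construct a RamanSpectrum
#'
#' @param wavenumber numeric wavenumber axis in cm^-1; rows are sorted if
#'   unordered, duplicate wavenumbers are an error.
#' @param intensity numeric intensities, same length.
#' @param region spectral region tag: `"fingerprint"`, `"thz"` or `"sers"`.
#' @param species species label (or `"mixture"`).
#' @param fraction nominal oxidized fraction in percent, or `NA` if unknown.
#' @param baselineCorrected,normalization processing-state flags.
#' @param extra named list merged into the metadata.
#' @return A validated [RamanSpectrum-class] object.
#' @examples
#' sp <- RamanSpectrum(seq(300, 1800, 0.5),
#'                     exp(-(seq(300, 1800, 0.5) - 1123)^2 / 128),
#'                     region = "fingerprint", species = "dGTP")
#' sp
#' @export
RamanSpectrum <- function(wavenumber, intensity, region,
                          species = "unknown", fraction = NA_real_,
                          baselineCorrected = FALSE, normalization = "none",
                          extra = list()) {
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]
  intensity <- intensity[o]
  if (anyDuplicated(wavenumber))
    stop("duplicate wavenumbers are not allowed")
  meta <- c(list(species = species, fraction = as.numeric(fraction),
                 region = region, baselineCorrected = baselineCorrected,
                 normalization = normalization), extra)
  new("RamanSpectrum", wavenumber = as.numeric(wavenumber),
      intensity = as.numeric(intensity), metadata = meta)
}

#' DeconvolutionResult: fitted Gaussian bands for one spectral window
#'
#' @slot window numeric(2), the fitted wavenumber interval (cm^-1).
#' @slot bands data.frame with columns `center`, `width`, `area`, their
#'   standard errors `centerSE`, `widthSE`, `areaSE`, and `assignment`.
#' @slot residualRMS root-mean-square of the fit residuals (intensity units).
#' @slot covariance parameter covariance matrix, 3 parameters per band in
#'   band order (center, width, area).
#' @slot converged logical; `FALSE` when the iteration limit was reached.
#' @aliases DeconvolutionResult-class
#' @exportClass DeconvolutionResult
setClass("DeconvolutionResult",
  slots = c(window = "numeric", bands = "data.frame", residualRMS = "numeric",
            covariance = "matrix", converged = "logical"))

setValidity("DeconvolutionResult", function(object) {
  b <- object@bands
  if (any(b$center < object@window[1] - 1e-9 | b$center > object@window[2] + 1e-9))
    return("fitted centers outside window")
  if (any(b$width <= 0)) return("widths must be > 0")
  if (any(b$area < 0)) return("areas must be >= 0")
  if (object@residualRMS < 0) return("residual RMS must be >= 0")
  TRUE
})

#' CalibrationCurve: linear marker-band calibration
#'
#' Houses the linear model I = m C + I0 relating a normalized marker-band
#' area I to the oxidized fraction C (percent). With contamination
#' correction the fitted intensity at C = 0 (the accidental oxidized content
#' of the nominally pure sample) is subtracted and the line refit through
#' the origin.
#'
#' @slot band marker label, e.g. `"1535"`, `"1607"`, `"620"` or `"averaged"`.
#' @slot slope,slopeSE slope m in normalized intensity per percent.
#' @slot intercept,interceptSE fitted intensity I0 at C = 0.
#' @slot sigmaRes residual standard deviation about the line.
#' @slot concRange numeric(2), percent range of the design.
#' @slot n number of calibration points.
#' @slot c0Corrected logical, whether the C0 correction was applied.
#' @aliases CalibrationCurve-class
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  slots = c(band = "character", slope = "numeric", slopeSE = "numeric",
            intercept = "numeric", interceptSE = "numeric",
            sigmaRes = "numeric", concRange = "numeric", n = "integer",
            c0Corrected = "logical"))

setValidity("CalibrationCurve", function(object) {
  if (object@n < 3L) return("calibration needs at least 3 points")
  if (object@sigmaRes < 0) return("sigmaRes must be >= 0")
  if (object@concRange[1] < 0 || object@concRange[2] > 100)
    return("concentration range must lie in [0, 100]")
  TRUE
})

#' ConcentrationEstimate: an inverse-predicted oxidized fraction
#'
#' @slot value estimated oxidized fraction, percent (may be negative; see
#'   `belowRange`).
#' @slot uncertainty standard uncertainty, percent.
#' @slot curve label of the calibration or model used.
#' @slot belowRange logical; `TRUE` when the raw estimate fell below 0%
#'   (reported, never silently clipped).
#' @aliases ConcentrationEstimate-class
#' @exportClass ConcentrationEstimate
setClass("ConcentrationEstimate",
  slots = c(value = "numeric", uncertainty = "numeric", curve = "character",
            belowRange = "logical"))

setValidity("ConcentrationEstimate", function(object) {
  if (object@uncertainty < 0) return("uncertainty must be >= 0")
  TRUE
})

#' TetradShiftModel: exponential THz main-band shift with oxidation
#'
#' The main low-frequency band of guanine nucleotides reflects collective
#' G-tetrad modes; oxidized fraction C shifts its center as
#' nu(C) = nu_8oxo + (nu_0 - nu_8oxo) exp(-C/R), where nu_0 and nu_8oxo are
#' the asymptotic frequencies of the non-oxidized and oxidized species and R
#' (percent) is the decay constant of tetrad disruption.
#'
#' @slot nu0,nu8oxo asymptotic main-band frequencies, cm^-1.
#' @slot decay decay constant R, percent (> 0).
#' @slot nu0SE,nu8oxoSE,decaySE standard errors (NA when not fitted).
#' @aliases TetradShiftModel-class
#' @exportClass TetradShiftModel
setClass("TetradShiftModel",
  slots = c(nu0 = "numeric", nu8oxo = "numeric", decay = "numeric",
            nu0SE = "numeric", nu8oxoSE = "numeric", decaySE = "numeric"))

setValidity("TetradShiftModel", function(object) {
  if (object@nu0 == object@nu8oxo) return("nu0 and nu8oxo must differ")
  if (object@decay <= 0) return("decay constant R must be > 0")
  TRUE
})

#' TetradShiftModel constructor
#'
#' @param nu0,nu8oxo asymptotic main-band frequencies (cm^-1) of the
#'   non-oxidized and fully oxidized species.
#' @param decay decay constant R in percent.
#' @param nu0SE,nu8oxoSE,decaySE optional standard errors.
#' @return A [TetradShiftModel-class] object.
#' @export
TetradShiftModel <- function(nu0, nu8oxo, decay,
                             nu0SE = NA_real_, nu8oxoSE = NA_real_,
                             decaySE = NA_real_) {
  new("TetradShiftModel", nu0 = nu0, nu8oxo = nu8oxo, decay = decay,
      nu0SE = nu0SE, nu8oxoSE = nu8oxoSE, decaySE = decaySE)
}

#' PLSModel: NIPALS PLS1 regression model for SERS spectra
#'
#' @slot nComponents number of latent components.
#' @slot weights,loadings p x A x-weight and x-loading matrices.
#' @slot yLoadings numeric(A) y-loadings.
#' @slot coefficients regression coefficient vector over the training grid.
#' @slot intercept scalar intercept on the original scale.
#' @slot xMean,yMean training means (grid-length vector, scalar).
#' @slot grid training wavenumber grid (cm^-1).
#' @slot window numeric(2) training window, cm^-1.
#' @slot scores n x A training score matrix.
#' @slot fitted,y training fitted values and responses (percent).
#' @aliases PLSModel-class
#' @exportClass PLSModel
setClass("PLSModel",
  slots = c(nComponents = "integer", weights = "matrix", loadings = "matrix",
            yLoadings = "numeric", coefficients = "numeric",
            intercept = "numeric", xMean = "numeric", yMean = "numeric",
            grid = "numeric", window = "numeric", scores = "matrix",
            fitted = "numeric", y = "numeric"))

setValidity("PLSModel", function(object) {
  if (object@nComponents < 1L) return("nComponents must be >= 1")
  if (length(object@coefficients) != length(object@grid))
    return("coefficient vector length must equal grid length")
  TRUE
})
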