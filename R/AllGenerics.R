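#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' `wavenumbers()` and `intensities()` return the axis and signal of a
#' [RamanSpectrum-class]; `spectrumInfo()` its metadata list;
#' `normalizationFactor()` the divisor stored by [normalizeToReference()].
#' `fittedBands()`, `residualRMS()` and `converged()` read a
#' [DeconvolutionResult-class].
#'
#' @param object a pipeline object.
#' @return The slot contents (vectors, list, data.frame or scalar as
#'   documented per accessor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("spectrumInfo", function(object) standardGeneric("spectrumInfo"))
#' @rdname accessors
#' @export
setGeneric("normalizationFactor",
           function(object) standardGeneric("normalizationFactor"))
#' @rdname accessors
#' @export
setGeneric("fittedBands", function(object) standardGeneric("fittedBands"))
#' @rdname accessors
#' @export
setGeneric("residualRMS", function(object) standardGeneric("residualRMS"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
setMethod("wavenumbers", "RamanSpectrum", function(object) object@wavenumber)
#' @rdname accessors
setMethod("intensities", "RamanSpectrum", function(object) object@intensity)
#' @rdname accessors
setMethod("spectrumInfo", "RamanSpectrum", function(object) object@metadata)
#' @rdname accessors
setMethod("normalizationFactor", "RamanSpectrum", function(object) {
  f <- object@metadata$normFactor
  if (is.null(f)) NA_real_ else f
})
#' @rdname accessors
setMethod("fittedBands", "DeconvolutionResult", function(object) object@bands)
#' @rdname accessors
setMethod("residualRMS", "DeconvolutionResult", function(object) object@residualRMS)
#' @rdname accessors
setMethod("converged", "DeconvolutionResult", function(object) object@converged)

#' @describeIn accessors number of points in the spectrum.
#' @param x a `RamanSpectrum`.
#' @export
setMethod("length", "RamanSpectrum", function(x) length(x@wavenumber))

setMethod("show", "RamanSpectrum", function(object) {
  m <- object@metadata
  cat(sprintf("RamanSpectrum: %s (%s), %d points, %.6g-%.6g cm-1\n",
              m$species,
              if (is.na(m$fraction)) "fraction unknown"
              else sprintf("%g%% oxidized", m$fraction),
              length(object@wavenumber),
              object@wavenumber[1], object@wavenumber[length(object@wavenumber)]))
  cat(sprintf("  region: %s | baseline-corrected: %s | normalization: %s\n",
              m$region, m$baselineCorrected, m$normalization))
  invisible(object)
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf("DeconvolutionResult: %d Gaussian band(s) in %.6g-%.6g cm-1\n",
              nrow(object@bands), object@window[1], object@window[2]))
  cat(sprintf("  residual RMS %.4g | converged: %s\n",
              object@residualRMS, object@converged))
  print(object@bands, digits = 5)
  invisible(object)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve [band %s]: I = %.5g * C + %.5g\n",
              object@band, object@slope, object@intercept))
  cat(sprintf("  slope SE %.3g | sigma_res %.3g | n = %d | C in [%g, %g]%% | C0-corrected: %s\n",
              object@slopeSE, object@sigmaRes, object@n,
              object@concRange[1], object@concRange[2], object@c0Corrected))
  invisible(object)
})

setMethod("show", "ConcentrationEstimate", function(object) {
  cat(sprintf("ConcentrationEstimate: C = %.4g +/- %.3g %% (curve %s)%s\n",
              object@value, object@uncertainty, object@curve,
              if (object@belowRange) " [below range]" else ""))
  invisible(object)
})

setMethod("show", "TetradShiftModel", function(object) {
  cat(sprintf("TetradShiftModel: nu(C) = %.4g + (%.4g - %.4g) exp(-C/%.4g)\n",
              object@nu8oxo, object@nu0, object@nu8oxo, object@decay))
  cat(sprintf("  SE: nu0 %.3g, nu8oxo %.3g, R %.3g\n",
              object@nu0SE, object@nu8oxoSE, object@decaySE))
  invisible(object)
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d component(s), %d wavenumbers in [%g, %g] cm-1, n = %d\n",
              object@nComponents, length(object@grid),
              object@window[1], object@window[2], length(object@y)))
  invisible(object)
})

#' @describeIn accessors regression/line coefficients of a calibration curve
#'   (`intercept`, `slope`).
#' @export
setMethod("coef", "CalibrationCurve", function(object)
  c(intercept = object@intercept, slope = object@slope))

#' @describeIn accessors model parameters of a tetrad-shift model
#'   (`nu0`, `nu8oxo`, `R`).
#' @export
setMethod("coef", "TetradShiftModel", function(object)
  c(nu0 = object@nu0, nu8oxo = object@nu8oxo, R = object@decay))

#' @describeIn accessors regression coefficient vector of a PLS model.
#' @export
setMethod("coef", "PLSModel", function(object) object@coefficients)
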