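# Exponential THz main-band shift model:
#   nu(C) = nu_8oxo + (nu_0 - nu_8oxo) * exp(-C / R)
# The main low-frequency band tracks G-tetrad assembly; oxidation disrupts
# the tetrads, relaxing the band from nu_0 toward nu_8oxo with decay
# constant R (percent). Sensitivity |d nu / d C| is maximal at C = 0, which
# is what makes this observable powerful at sub-percent oxidized fractions.

#' Evaluate the tetrad-shift model
#'
#' @param model a [TetradShiftModel-class].
#' @param C oxidized fraction(s), percent.
#' @return Main-band frequency nu(C), cm^-1.
#' @export
shiftFrequency <- function(model, C) {
  stopifnot(is(model, "TetradShiftModel"))
  model@nu8oxo + (model@nu0 - model@nu8oxo) * exp(-C / model@decay)
}

#' Fit the exponential tetrad-shift model
#'
#' Least-squares fit of `nu(C) = nu_8oxo + (nu_0 - nu_8oxo) exp(-C/R)` to
#' main-band centers extracted by [thzMainBand()] (weighted by `1/err^2`
#' when errors are supplied). Initialization: nu_0 from the lowest-C point,
#' nu_8oxo from the highest-C point, R from a log-linearized two-point
#' estimate.
#'
#' @param points data.frame with columns `C` (percent), `nu` (cm^-1) and
#'   optionally `err`.
#' @return A [TetradShiftModel-class] with standard errors.
#' @examples
#' truth <- TetradShiftModel(95, 60, 6)
#' C <- c(0, 1, 2, 4, 8, 16)
#' fitExponential(data.frame(C = C, nu = shiftFrequency(truth, C)))
#' @export
fitExponential <- function(points) {
  stopifnot(all(c("C", "nu") %in% names(points)))
  C <- points$C; nu <- points$nu
  if (length(unique(C)) < 4L)
    stop("need at least 4 distinct concentrations to constrain the model")
  if (diff(range(nu)) < 1e-9 * max(1, abs(nu[1])))
    stop("degenerate input: all frequencies equal, R is unbounded")
  o <- order(C)
  nu0i <- nu[o][1L]
  nu8i <- nu[o][length(o)]
  # log-linearized two-point estimate of R using an interior point
  mid <- o[ceiling(length(o) / 2)]
  z <- (nu[mid] - nu8i) / (nu0i - nu8i)
  Ri <- if (is.finite(z) && z > 0 && z < 1) -C[mid] / log(z) else max(C) / 3
  if (!is.finite(Ri) || Ri <= 0) Ri <- max(C) / 3
  wts <- if ("err" %in% names(points) && all(is.finite(points$err)) &&
             all(points$err > 0)) 1 / points$err^2 else NULL
  df <- data.frame(C = C, nu = nu)
  args <- list(
    nu ~ nu8 + (nu0 - nu8) * exp(-C / R), data = df,
    start = list(nu0 = nu0i, nu8 = nu8i, R = Ri),
    lower = c(-Inf, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  if (!is.null(wts)) args$weights <- wts
  fit <- do.call(minpack.lm::nlsLM, args)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  TetradShiftModel(nu0 = cf[["nu0"]], nu8oxo = cf[["nu8"]], decay = cf[["R"]],
                   nu0SE = se[["nu0"]], nu8oxoSE = se[["nu8"]],
                   decaySE = se[["R"]])
}

#' Invert the tetrad-shift model
#'
#' `C = -R log((nu - nu_8oxo) / (nu_0 - nu_8oxo))`, with first-order
#' propagation of the frequency error and the model parameter errors
#' (treated as uncorrelated). The frequency must lie strictly between the
#' asymptotes (it may equal nu_0, giving C = 0).
#'
#' @param model a [TetradShiftModel-class].
#' @param nu measured main-band frequency, cm^-1.
#' @param nuErr its standard error (0 when unknown).
#' @return A [ConcentrationEstimate-class].
#' @examples
#' m <- TetradShiftModel(95, 60, 6)
#' predictConcentrationThz(m, 60 + 35 * exp(-1))  # C = 6%
#' @export
predictConcentrationThz <- function(model, nu, nuErr = 0) {
  stopifnot(is(model, "TetradShiftModel"))
  nu0 <- model@nu0; nu8 <- model@nu8oxo; R <- model@decay
  z <- (nu - nu8) / (nu0 - nu8)
  if (!is.finite(z) || z <= 0 || z > 1)
    stop(sprintf("frequency %g cm-1 outside the model range (%g, %g]",
                 nu, min(nu0, nu8), max(nu0, nu8)))
  C <- -R * log(z)
  dC_dnu <- -R / (nu - nu8)
  dC_dnu0 <- R / (nu0 - nu8)
  dC_dnu8 <- -R * (-1 / (nu - nu8) + 1 / (nu0 - nu8))
  dC_dR <- C / R
  ses <- c(model@nu0SE, model@nu8oxoSE, model@decaySE)
  ses[!is.finite(ses)] <- 0
  u <- sqrt((dC_dnu * nuErr)^2 + (dC_dnu0 * ses[1])^2 +
            (dC_dnu8 * ses[2])^2 + (dC_dR * ses[3])^2)
  new("ConcentrationEstimate", value = C, uncertainty = u,
      curve = "thz-exponential", belowRange = C < 0)
}

#' Fit the tetrad-shift model from a THz spectrum series
#'
#' Convenience wrapper: linear baseline subtraction (when needed),
#' main-band extraction via [thzMainBand()] for every spectrum, and
#' [fitExponential()] on the resulting (C, nu) points.
#'
#' @param spectra list of THz [RamanSpectrum-class] objects.
#' @param fractions their oxidized fractions, percent.
#' @return list with `model` (a [TetradShiftModel-class]) and `points`.
#' @export
fitThzSeries <- function(spectra, fractions) {
  stopifnot(length(spectra) == length(fractions))
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    if (!isTRUE(spectrumInfo(sp)$baselineCorrected))
      sp <- subtractBaseline(sp, "linear")
    mb <- thzMainBand(sp)
    data.frame(C = fractions[i], nu = mb$center, err = mb$se)
  })
  pts <- do.call(rbind, rows)
  list(model = fitExponential(pts), points = pts)
}
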