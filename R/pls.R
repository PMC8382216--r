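# PLS1 regression by NIPALS with deflation, for SERS quantification of the
# oxidized fraction. Deterministic: the first weight vector is the
# response-covariance direction, no random initialization. Implemented
# in-repo; an established PLS library serves only as a test oracle.

# Core NIPALS PLS1 on a centered matrix Xc and centered response yc.
nipalsPLS1 <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  X <- Xc; y <- yc
  for (a in seq_len(A)) {
    wv <- drop(crossprod(X, y))
    nw <- sqrt(sum(wv^2))
    if (nw < .Machine$double.eps)
      stop("rank error: response covariance vanished at component ", a)
    wv <- wv / nw
    tv <- drop(X %*% wv)
    tt <- sum(tv^2)
    if (tt < .Machine$double.eps)
      stop("rank error: zero-variance score at component ", a)
    pv <- drop(crossprod(X, tv)) / tt
    qa <- sum(y * tv) / tt
    X <- X - tcrossprod(tv, pv)
    y <- y - qa * tv
    W[, a] <- wv; P[, a] <- pv; Tm[, a] <- tv; q[a] <- qa
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, scores = Tm, q = q, coef = drop(B))
}

#' Fit a PLS1 model to SERS spectra
#'
#' Unit-vector normalizes every spectrum to the training window
#' (400--1800 cm^-1 by default, which excludes the colloid band near
#' 240 cm^-1), verifies that all spectra share one wavenumber grid (no
#' silent resampling), mean-centers, and runs NIPALS PLS1 with the given
#' number of latent components (3 by default). No variance scaling is
#' applied: the spectra share units.
#'
#' @param spectra list of [RamanSpectrum-class] objects.
#' @param fractions oxidized fractions, percent.
#' @param nComponents number of latent components (default 3).
#' @param window training window, cm^-1.
#' @return A [PLSModel-class].
#' @export
fitPLS <- function(spectra, fractions, nComponents = 3, window = c(400, 1800)) {
  stopifnot(length(spectra) == length(fractions))
  if (length(spectra) < nComponents + 1L)
    stop("need at least nComponents + 1 spectra")
  norm <- lapply(spectra, function(sp)
    if (identical(spectrumInfo(sp)$normalization, "unit-vector")) sp
    else unitVectorNormalize(sp, window))
  grid <- wavenumbers(norm[[1L]])
  for (sp in norm[-1L])
    if (length(wavenumbers(sp)) != length(grid) ||
        any(wavenumbers(sp) != grid))
      stop("grid error: spectra do not share a common wavenumber grid")
  X <- do.call(rbind, lapply(norm, intensities))
  y <- as.numeric(fractions)
  if (nComponents > qr(scale(X, center = TRUE, scale = FALSE))$rank)
    stop("rank error: nComponents exceeds the rank of the training matrix")
  xm <- colMeans(X); ym <- mean(y)
  fit <- nipalsPLS1(sweep(X, 2L, xm), y - ym, as.integer(nComponents))
  fitted <- drop(sweep(X, 2L, xm) %*% fit$coef) + ym
  new("PLSModel", nComponents = as.integer(nComponents),
      weights = fit$W, loadings = fit$P, yLoadings = fit$q,
      coefficients = fit$coef, intercept = ym - sum(xm * fit$coef),
      xMean = xm, yMean = ym, grid = grid, window = as.numeric(window),
      scores = fit$scores, fitted = fitted, y = y)
}

#' Predict an oxidized fraction from a SERS spectrum
#'
#' Applies unit-vector normalization over the training window, checks the
#' grid against the training grid, and evaluates the regression vector.
#' Predictions may fall outside [0, 100]; they are flagged via the
#' `"outOfRange"` attribute, never clipped.
#'
#' @param model a [PLSModel-class].
#' @param spectrum a [RamanSpectrum-class] covering the training window.
#' @return Predicted oxidized fraction, percent.
#' @export
predictPLS <- function(model, spectrum) {
  stopifnot(is(model, "PLSModel"), is(spectrum, "RamanSpectrum"))
  sp <- if (identical(spectrumInfo(spectrum)$normalization, "unit-vector"))
    spectrum else unitVectorNormalize(spectrum, model@window)
  g <- wavenumbers(sp)
  if (length(g) != length(model@grid) || any(g != model@grid))
    stop("grid error: spectrum grid differs from the training grid")
  pred <- model@intercept + sum(intensities(sp) * model@coefficients)
  attr(pred, "outOfRange") <- pred < 0 || pred > 100
  pred
}

#' Leave-one-out cross-validation of the PLS quantification
#'
#' Refits the model with each spectrum held out in turn and predicts it,
#' giving the predicted-vs-actual table and the root-mean-square error of
#' cross-validation (RMSECV). Deterministic.
#'
#' @param spectra list of [RamanSpectrum-class] objects (>= 4).
#' @param fractions oxidized fractions, percent.
#' @param nComponents latent components (default 3).
#' @param window training window, cm^-1.
#' @return list with `predictions` (data.frame `actual`, `predicted`,
#'   `residual`) and `rmsecv` (percent).
#' @export
crossValidatePLS <- function(spectra, fractions, nComponents = 3,
                             window = c(400, 1800)) {
  n <- length(spectra)
  if (n < 4L) stop("need at least 4 spectra for cross-validation")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- fitPLS(spectra[-i], fractions[-i], nComponents, window)
    pred[i] <- as.numeric(predictPLS(m, spectra[[i]]))
  }
  resid <- pred - fractions
  list(predictions = data.frame(actual = fractions, predicted = pred,
                                residual = resid),
       rmsecv = sqrt(mean(resid^2)))
}
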