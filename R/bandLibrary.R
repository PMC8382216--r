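#' Default vibrational band library
#'
#' Named list, one data.frame per species, with columns `center` (cm^-1),
#' `width` (Gaussian sigma, cm^-1), `area` (normalized arbitrary units),
#' `assignment` and `region` (`"fingerprint"`, `"thz"` or `"sers"`).
#'
#' Fingerprint assignments follow the standard band list for purine
#' nucleotides: the phosphate-backbone stretch at 1123 cm^-1 (used for
#' normalization), dGTP/GTP ring modes at 1485 and 1575 cm^-1, the 8-oxo
#' markers at 1445, 1535 (band A) and 1607 cm^-1 (band B), the 8-oxo-dATP
#' C5-N7-C8 squeezing marker at 620 cm^-1, and the silver-colloid band near
#' 240 cm^-1 in SERS. THz entries carry the single broad collective band of
#' each species (95 cm^-1 for dGTP with intact G-tetrads, 60 cm^-1 for
#' 8-oxo-dGTP where tetrad assembly is disrupted).
#'
#' Band widths and absolute areas are generator parameters, not measured
#' quantities: sigma defaults to 8 cm^-1 (fingerprint) and 25 cm^-1 (THz
#' broad band). The phosphate reference area is scaled so that its
#' trapezoidal integral over the default +/-15 cm^-1 normalization window is
#' exactly 1; marker areas 0.8 (band A) and 0.9 (band B) then correspond to
#' calibration slopes 0.008 and 0.009 normalized intensity per percent under
#' linear mixing.
#'
#' @return Named list of band data.frames.
#' @examples
#' lib <- defaultBandLibrary()
#' lib[["8-oxo-dGTP"]]
#' @export
defaultBandLibrary <- function() {
  # phosphate band area such that its +/-15 cm-1 trapezoidal integral is 1
  poArea <- 1 / (2 * stats::pnorm(15 / 8) - 1)
  band <- function(center, width, area, assignment, region = "fingerprint")
    data.frame(center = center, width = width, area = area,
               assignment = assignment, region = region,
               stringsAsFactors = FALSE)
  gtpFinger <- rbind(
    band(681,  8, 0.55, "guanine ring breathing"),
    band(1123, 8, poArea, "PO4 backbone stretch (normalization)"),
    band(1325, 8, 0.45, "guanine C-N stretch"),
    band(1485, 8, 0.85, "7N-8C stretch"),
    band(1575, 8, 0.60, "3N-4C stretch"))
  oxoGtpFinger <- rbind(
    band(690,  8, 0.50, "ring breathing"),
    band(1123, 8, poArea, "PO4 backbone stretch (normalization)"),
    band(1445, 8, 0.60, "7N-H bend"),
    band(1535, 8, 0.80, "7N-8C stretch (marker A)"),
    band(1607, 8, 0.90, "5C-7N stretch (marker B)"))
  list(
    "dGTP" = rbind(gtpFinger,
      band(95, 25, 1.0, "G-tetrad collective mode", "thz")),
    "8-oxo-dGTP" = rbind(oxoGtpFinger,
      band(60, 25, 1.0, "disrupted-assembly collective mode", "thz")),
    "GTP" = rbind(gtpFinger,
      band(92, 25, 1.0, "G-tetrad collective mode", "thz")),
    "8-oxo-GTP" = rbind(oxoGtpFinger,
      band(61, 25, 1.0, "disrupted-assembly collective mode", "thz")),
    "dATP" = rbind(
      band(730,  8, 0.90, "adenine ring breathing"),
      band(1123, 8, poArea, "PO4 backbone stretch (normalization)"),
      band(1339, 8, 0.60, "adenine C-N stretch"),
      band(1580, 8, 0.50, "ring stretch")),
    "8-oxo-dATP" = rbind(
      band(620,  8, 0.70, "C5-N7-C8 squeeze (oxidation marker)"),
      band(730,  8, 0.45, "adenine ring breathing"),
      band(1123, 8, poArea, "PO4 backbone stretch (normalization)"),
      band(1445, 8, 0.40, "7N-H bend"),
      band(1601, 8, 0.45, "ring stretch")),
    "dG" = rbind(
      band(500,  8, 0.30, "sugar deformation", "sers"),
      band(682,  8, 0.80, "guanine ring breathing", "sers"),
      band(1325, 8, 0.55, "guanine C-N stretch", "sers"),
      band(1489, 8, 0.90, "7N-8C stretch", "sers"),
      band(1577, 8, 0.50, "3N-4C stretch", "sers")),
    "8-oxo-dG" = rbind(
      band(645,  8, 0.45, "ring deformation", "sers"),
      band(1250, 8, 0.60, "ring/N-H mode", "sers"),
      band(1445, 8, 0.50, "7N-H bend", "sers"),
      band(1535, 8, 0.75, "7N-8C stretch (marker A)", "sers"),
      band(1610, 8, 0.70, "5C-7N stretch (marker B)", "sers")),
    "colloid" = band(240, 20, 1.50, "Ag colloid characteristic band", "sers")
  )
}

#' Default THz tetrad-shift models
#'
#' Placeholder asymptotes and decay constants consistent with the observed
#' behaviour of guanine nucleotides: a > 30 cm^-1 main-band shift between the
#' pure species, and different decay rates R for deoxyribo- and
#' ribonucleotides (the sugar modulates long-range intermolecular
#' interactions). The deoxy asymptotes match the default THz band-library
#' centers for dGTP/8-oxo-dGTP.
#'
#' @param kind `"deoxy"` (dGTP/8-oxo-dGTP) or `"ribo"` (GTP/8-oxo-GTP).
#' @return A [TetradShiftModel-class].
#' @export
defaultTetradShiftModel <- function(kind = c("deoxy", "ribo")) {
  kind <- match.arg(kind)
  if (kind == "deoxy") TetradShiftModel(nu0 = 95, nu8oxo = 60, decay = 6)
  else TetradShiftModel(nu0 = 92, nu8oxo = 61, decay = 3)
}

# Validate a band data.frame; used by the generator.
checkBands <- function(bands, species) {
  need <- c("center", "width", "area")
  if (!all(need %in% names(bands)))
    stop("band table for ", species, " must have columns center, width, area")
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$area < 0)) stop("band areas must be >= 0")
  invisible(bands)
}
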