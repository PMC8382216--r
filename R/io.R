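#' Read a spectrum from a two-column text file
#'
#' Accepts whitespace- or comma-separated numeric columns (wavenumber cm^-1,
#' intensity) with optional `# key: value` header lines as written by
#' [writeSpectrum()]. Rows are sorted by wavenumber if the file is unsorted;
#' duplicate wavenumbers are an error (silent averaging would hide
#' instrument faults).
#'
#' @param path file to read.
#' @param region region tag (`"fingerprint"`, `"thz"`, `"sers"`); if `NULL`,
#'   taken from the file header.
#' @param minPoints minimum number of data rows required (default 8).
#' @return A [RamanSpectrum-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' sp <- generatePureSpectrum("dGTP", seed = 1)
#' writeSpectrum(sp, f)
#' sp2 <- readSpectrum(f)
#' all.equal(wavenumbers(sp), wavenumbers(sp2))
#' @export
readSpectrum <- function(path, region = NULL, minPoints = 8L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- list()
  dataLines <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
      if (length(m) == 3L) header[[trimws(m[2])]] <- trimws(m[3])
      next
    }
    dataLines <- c(dataLines, i)
  }
  if (length(dataLines) < minPoints)
    stop(sprintf("too short: %d data rows in %s (minimum %d)",
                 length(dataLines), path, minPoints))
  w <- numeric(length(dataLines)); y <- numeric(length(dataLines))
  for (k in seq_along(dataLines)) {
    i <- dataLines[k]
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop(sprintf("malformed row at line %d of %s: '%s'", i, path, lines[i]))
    if (!all(is.finite(vals[1:2])))
      stop(sprintf("non-finite value at line %d of %s", i, path))
    w[k] <- vals[1]; y[k] <- vals[2]
  }
  region <- region %||% header$region
  if (is.null(region)) stop("no region tag in header and none supplied")
  fraction <- if (!is.null(header$fraction_pct)) {
    fv <- suppressWarnings(as.numeric(header$fraction_pct))
    fv
  } else NA_real_
  RamanSpectrum(w, y, region = region,
                species = header$species %||% "unknown",
                fraction = fraction,
                baselineCorrected = identical(header$baseline_corrected, "TRUE"),
                normalization = header$normalization %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum to a two-column text file
#'
#' Writes `# key: value` metadata header lines followed by fixed-format
#' numeric columns, re-readable by [readSpectrum()].
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  m <- spectrum@metadata
  hdr <- c(
    sprintf("# species: %s", m$species),
    sprintf("# fraction_pct: %s",
            if (is.na(m$fraction)) "NA" else format(m$fraction, digits = 10)),
    sprintf("# region: %s", m$region),
    sprintf("# baseline_corrected: %s", m$baselineCorrected),
    sprintf("# normalization: %s", m$normalization))
  rows <- sprintf("%.4f %.10e", spectrum@wavenumber, spectrum@intensity)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Load a dataset manifest
#'
#' A manifest is a CSV with header `path,species,fraction_pct,replicate`
#' describing a series of spectrum files. Relative paths are resolved
#' against the manifest location; every referenced file must exist and
#' fractions must lie in [0, 100] (or be NA for unknowns).
#'
#' @param path manifest CSV.
#' @return data.frame with columns `path` (absolute), `species`,
#'   `fraction_pct`, `replicate`.
#' @export
loadManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "species", "fraction_pct", "replicate")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$path)) stop("duplicate paths in manifest")
  bad <- !is.na(df$fraction_pct) & (df$fraction_pct < 0 | df$fraction_pct > 100)
  if (any(bad))
    stop("fractions outside [0, 100]: ",
         paste(df$fraction_pct[bad], collapse = ", "))
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  missing <- abs[!file.exists(abs)]
  if (length(missing))
    stop("missing spectrum files: ", paste(missing, collapse = ", "))
  df$path <- abs
  df
}

#' Write a dataset manifest
#'
#' @param manifest data.frame with columns `path`, `species`,
#'   `fraction_pct`, `replicate`.
#' @param path output CSV; spectrum paths are stored relative to it when
#'   they live in the same directory.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  base <- dirname(path)
  rel <- manifest$path
  inBase <- dirname(rel) == normalizePath(base, mustWork = FALSE) |
    dirname(rel) == base
  rel[inBase] <- basename(rel[inBase])
  out <- manifest
  out$path <- rel
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
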