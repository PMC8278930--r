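#' Sample metadata for mean residue ellipticity conversion
#'
#' Bundles the sample quantities needed to convert raw ellipticity
#' (millidegrees) into mean residue ellipticity (MRE): protein mass
#' concentration, cuvette path length, molar mass and residue count.
#'
#' @param protein_conc Protein mass concentration, mg/mL. Must be > 0.
#' @param pathlength Cuvette path length, cm. Must be > 0.
#' @param molecular_weight Protein molar mass, g/mol. Must be > 0.
#' @param n_residues Number of amino-acid residues (>= 2).
#' @param label Free-text formulation name, e.g. \code{"F1IL"}.
#' @return An object of class \code{"sample_meta"}.
#' @examples
#' sample_meta(1, 0.1, 146000, 1320, label = "IgG4/water")
#' @export
sample_meta <- function(protein_conc, pathlength, molecular_weight,
                        n_residues, label = "sample") {
  check_number(protein_conc, "protein_conc", positive = TRUE)
  check_number(pathlength, "pathlength", positive = TRUE)
  check_number(molecular_weight, "molecular_weight", positive = TRUE)
  check_number(n_residues, "n_residues")
  if (n_residues < 2 || n_residues != round(n_residues))
    stopf("'n_residues' must be an integer >= 2", class = "mabtherm_validation_error")
  structure(list(protein_conc = protein_conc, pathlength = pathlength,
                 molecular_weight = molecular_weight,
                 n_residues = as.integer(n_residues),
                 label = as.character(label)),
            class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("Sample '%s': %.3g mg/mL, path %.3g cm, MW %.6g g/mol, %d residues\n",
              x$label, x$protein_conc, x$pathlength, x$molecular_weight,
              x$n_residues))
  invisible(x)
}

#' Temperature-resolved CD spectrum series
#'
#' Container for variable-temperature CD data: an ellipticity matrix indexed
#' by temperature (rows) and wavelength (columns), with units flag and sample
#' metadata.
#'
#' @param temperatures Strictly increasing temperatures, degrees C.
#' @param wavelengths Strictly monotone wavelength grid, nm.
#' @param signal Numeric matrix, \code{length(temperatures)} x
#'   \code{length(wavelengths)}, in millidegrees or MRE per \code{units}.
#' @param units One of \code{"millidegrees"} or \code{"MRE"}.
#' @param meta A [sample_meta()] object, or \code{NULL}.
#' @return An object of class \code{"cd_series"}.
#' @export
cd_spectrum_series <- function(temperatures, wavelengths, signal,
                               units = c("millidegrees", "MRE"), meta = NULL) {
  units <- match.arg(units)
  temperatures <- as.numeric(temperatures)
  wavelengths <- as.numeric(wavelengths)
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is_strictly_increasing(temperatures))
    stopf("temperatures must be strictly increasing (duplicate or unsorted values)",
          class = "mabtherm_validation_error")
  dl <- diff(wavelengths)
  if (length(wavelengths) > 1 && !(all(dl > 0) || all(dl < 0)))
    stopf("wavelengths must be strictly monotone", class = "mabtherm_validation_error")
  if (!identical(dim(signal), c(length(temperatures), length(wavelengths))))
    stopf("signal must be a %d x %d matrix (got %d x %d)",
          length(temperatures), length(wavelengths), nrow(signal), ncol(signal),
          class = "mabtherm_validation_error")
  if (any(!is.finite(signal)))
    stopf("signal contains non-finite entries; missing values are rejected, not imputed",
          class = "mabtherm_validation_error")
  if (!is.null(meta) && !inherits(meta, "sample_meta"))
    stopf("'meta' must be a sample_meta object or NULL", class = "mabtherm_validation_error")
  structure(list(temperatures = temperatures, wavelengths = wavelengths,
                 signal = signal, units = units, meta = meta),
            class = "cd_series")
}

#' @export
print.cd_series <- function(x, ...) {
  cat(sprintf("CD spectrum series: %d temperatures (%.4g-%.4g degC), %d wavelengths (%g-%g nm), units %s\n",
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$units))
  if (!is.null(x$meta)) print(x$meta)
  invisible(x)
}

#' Single-wavelength melt signal
#'
#' CD signal at one wavelength as a function of temperature; the input of the
#' beta-sheet-fraction computation.
#'
#' @param temperatures Strictly increasing temperatures, degrees C.
#' @param y CD signal at \code{wavelength} (MRE or millidegrees).
#' @param wavelength Wavelength, nm (218 by default, the beta-sheet band).
#' @param units Signal units flag.
#' @param meta Optional [sample_meta()].
#' @return An object of class \code{"melt_signal"}.
#' @export
melt_signal <- function(temperatures, y, wavelength = 218,
                        units = c("MRE", "millidegrees"), meta = NULL) {
  units <- match.arg(units)
  temperatures <- as.numeric(temperatures)
  y <- as.numeric(y)
  if (length(temperatures) != length(y))
    stopf("temperatures and y must have equal length", class = "mabtherm_validation_error")
  if (!is_strictly_increasing(temperatures))
    stopf("temperatures must be strictly increasing", class = "mabtherm_validation_error")
  if (any(!is.finite(y)))
    stopf("y contains non-finite values", class = "mabtherm_validation_error")
  structure(list(temperatures = temperatures, y = y,
                 wavelength = as.numeric(wavelength), units = units, meta = meta),
            class = "melt_signal")
}

#' @export
print.melt_signal <- function(x, ...) {
  cat(sprintf("Melt signal at %g nm: %d points, %.4g-%.4g degC (%s)\n",
              x$wavelength, length(x$y), min(x$temperatures),
              max(x$temperatures), x$units))
  invisible(x)
}

## sniff the field separator of a delimited text file (comma vs tab)
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stopf("'%s' is empty", path, class = "mabtherm_parse_error")
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab > n_com) "\t" else ","
}

#' Read a temperature x wavelength CD melt matrix from CSV/TSV
#'
#' Expects one header row whose first column is temperature in degrees C
#' (any name) and whose remaining column names are numeric wavelengths in nm.
#' Comma- or tab-separated files are accepted (sniffed from the header).
#' Rows are sorted by temperature; duplicate temperatures are an error.
#'
#' @param path Path to the file.
#' @param units Units of the stored values.
#' @param meta Optional [sample_meta()] attached to the result.
#' @return A [cd_spectrum_series()].
#' @export
read_melt_csv <- function(path, units = c("millidegrees", "MRE"), meta = NULL) {
  units <- match.arg(units)
  if (!file.exists(path))
    stopf("file '%s' does not exist", path, class = "mabtherm_io_error")
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L)
    stopf("'%s': need a temperature column plus at least one wavelength column",
          path, class = "mabtherm_parse_error")
  wl_names <- names(df)[-1L]
  wl <- suppressWarnings(as.numeric(wl_names))
  if (any(is.na(wl)))
    stopf("malformed header: column '%s' is not a numeric wavelength",
          wl_names[which(is.na(wl))[1L]], class = "mabtherm_parse_error")
  num <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(df[[j]]))
    if (length(bad) || anyNA(v))
      if (length(bad))
        stopf("non-numeric value '%s' at data row %d, column '%s'",
              df[[j]][bad[1L]], bad[1L], names(df)[j], class = "mabtherm_parse_error")
      else
        stopf("missing value at data row %d, column '%s'",
              which(is.na(v))[1L], names(df)[j], class = "mabtherm_parse_error")
    num[, j] <- v
  }
  temp <- num[, 1L]
  if (anyDuplicated(temp))
    stopf("duplicate temperature %g degC in '%s'", temp[duplicated(temp)][1L],
          path, class = "mabtherm_validation_error")
  ord <- order(temp)
  cd_spectrum_series(temp[ord], wl, num[ord, -1L, drop = FALSE],
                     units = units, meta = meta)
}

#' Write a CD melt matrix to CSV
#'
#' Inverse of [read_melt_csv()]: writes `temperature_C` plus one column per
#' wavelength. Round-trips numeric values at full double precision.
#'
#' @param series A [cd_spectrum_series()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_melt_csv <- function(series, path) {
  stopifnot(inherits(series, "cd_series"))
  df <- data.frame(temperature_C = series$temperatures,
                   series$signal, check.names = FALSE)
  names(df) <- c("temperature_C", format(series$wavelengths, trim = TRUE, digits = 15))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-wavelength melt series from CSV/TSV
#'
#' Expects columns \code{temperature_C, signal} (names are not checked beyond
#' position). Rows are sorted by temperature; duplicates are rejected.
#'
#' @inheritParams read_melt_csv
#' @param wavelength Wavelength the series was recorded at, nm.
#' @return A [melt_signal()].
#' @export
read_melt_signal_csv <- function(path, wavelength = 218,
                                 units = c("MRE", "millidegrees"), meta = NULL) {
  units <- match.arg(units)
  if (!file.exists(path))
    stopf("file '%s' does not exist", path, class = "mabtherm_io_error")
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(df) < 2L)
    stopf("'%s': need temperature and signal columns", path,
          class = "mabtherm_parse_error")
  temp <- as.numeric(df[[1L]]); y <- as.numeric(df[[2L]])
  if (anyNA(temp) || anyNA(y))
    stopf("non-numeric cell in '%s'", path, class = "mabtherm_parse_error")
  if (anyDuplicated(temp))
    stopf("duplicate temperature in '%s'", path, class = "mabtherm_validation_error")
  ord <- order(temp)
  melt_signal(temp[ord], y[ord], wavelength = wavelength, units = units,
              meta = meta)
}

#' Extract a single-wavelength melt signal from a spectrum series
#'
#' Returns the column nearest the requested wavelength (exact match
#' preferred); the wavelength actually used is recorded on the result.
#'
#' @param series A [cd_spectrum_series()].
#' @param wavelength Requested wavelength, nm; must lie within the measured
#'   range.
#' @return A [melt_signal()] carrying the grid wavelength actually used.
#' @export
extract_wavelength <- function(series, wavelength = 218) {
  stopifnot(inherits(series, "cd_series"))
  wl <- series$wavelengths
  if (wavelength < min(wl) || wavelength > max(wl))
    stopf("wavelength %g nm outside measured range [%g, %g]",
          wavelength, min(wl), max(wl), class = "mabtherm_range_error")
  j <- which.min(abs(wl - wavelength))
  melt_signal(series$temperatures, series$signal[, j], wavelength = wl[j],
              units = if (series$units == "MRE") "MRE" else "millidegrees",
              meta = series$meta)
}
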