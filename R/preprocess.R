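#' Preprocessing configuration for CD spectra
#'
#' Defaults mirror standard CD data treatment: zeroing against the featureless
#' 250-260 nm region and Savitzky-Golay smoothing with a 7-point window of
#' polynomial order 5 along the wavelength axis.
#'
#' @param zero_window Length-2 wavelength interval (nm) used for zeroing.
#' @param sg_window Odd Savitzky-Golay window length (points).
#' @param sg_order Savitzky-Golay polynomial order; \code{sg_window} must be
#'   odd and at least \code{sg_order + 1}.
#' @param smooth_temperature Logical; also smooth along the temperature axis
#'   (off by default, smoothing acts along wavelength only).
#' @return A list of class \code{"preprocess_config"}.
#' @export
preprocess_config <- function(zero_window = c(250, 260), sg_window = 7,
                              sg_order = 5, smooth_temperature = FALSE) {
  if (length(zero_window) != 2L || zero_window[1] >= zero_window[2])
    stopf("zero_window must be an increasing length-2 interval",
          class = "mabtherm_validation_error")
  if (sg_window %% 2 != 1 || sg_window < sg_order + 1)
    stopf("sg_window must be odd and >= sg_order + 1",
          class = "mabtherm_validation_error")
  structure(list(zero_window = as.numeric(zero_window),
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 smooth_temperature = isTRUE(smooth_temperature)),
            class = "preprocess_config")
}

#' Subtract an averaged background spectrum
#'
#' Subtracts a matrix-only background (typically the mean of replicate blank
#' spectra, see [average_background()]) from every temperature slice.
#'
#' @param series A [cd_spectrum_series()].
#' @param background Numeric vector on the same wavelength grid, or a
#'   \code{cd_series} whose spectra are averaged first.
#' @return The background-corrected \code{cd_series}; metadata unchanged.
#' @export
subtract_background <- function(series, background) {
  stopifnot(inherits(series, "cd_series"))
  if (inherits(background, "cd_series")) {
    if (!isTRUE(all.equal(background$wavelengths, series$wavelengths)))
      stopf("background wavelength grid does not match the series grid",
            class = "mabtherm_validation_error")
    background <- colMeans(background$signal)
  }
  background <- as.numeric(background)
  if (length(background) != length(series$wavelengths))
    stopf("background length %d does not match the %d-point wavelength grid",
          length(background), length(series$wavelengths),
          class = "mabtherm_validation_error")
  out <- series
  out$signal <- sweep(series$signal, 2L, background, `-`)
  out
}

#' Average replicate background spectra
#'
#' Arithmetic mean over replicates, computed before subtraction.
#'
#' @param replicates A list of numeric vectors (one spectrum each) or a
#'   matrix with one replicate per row.
#' @return A numeric vector, the averaged background spectrum.
#' @export
average_background <- function(replicates) {
  if (is.list(replicates)) replicates <- do.call(rbind, replicates)
  colMeans(as.matrix(replicates))
}

#' Zero spectra against a high-wavelength window
#'
#' For each temperature, subtracts the mean signal over the window from that
#' temperature's whole spectrum, so the per-temperature window mean becomes 0.
#' Idempotent.
#'
#' @param series A [cd_spectrum_series()].
#' @param window Length-2 wavelength interval, nm; must contain at least two
#'   grid points.
#' @return The zeroed \code{cd_series}.
#' @export
zero_high_wavelength <- function(series, window = c(250, 260)) {
  stopifnot(inherits(series, "cd_series"))
  idx <- which(series$wavelengths >= min(window) & series$wavelengths <= max(window))
  if (length(idx) < 2L)
    stopf("zeroing window [%g, %g] nm contains %d grid point(s); need >= 2",
          min(window), max(window), length(idx),
          class = "mabtherm_validation_error")
  offs <- rowMeans(series$signal[, idx, drop = FALSE])
  out <- series
  out$signal <- series$signal - offs
  out
}

## Savitzky-Golay smoothing of one vector. Interior points use the central
## window; each edge point is the value at its position of the order-p
## polynomial least-squares fitted to the first (last) `window` points --
## i.e. the largest available one-sided window, no padding. This matches
## signal::sgolayfilt's transient handling, which we rely on.
sg_smooth_vec <- function(y, window, order) {
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

#' Savitzky-Golay smoothing along the wavelength axis
#'
#' Each temperature slice is replaced by its Savitzky-Golay filtered version.
#' Edge points are handled by evaluating the polynomial fitted to the
#' first/last full window at the edge positions (no padding, no fabricated
#' data outside the measured range). Polynomials of degree at most
#' \code{order} are reproduced exactly.
#'
#' @param series A [cd_spectrum_series()].
#' @param window Odd window length in points (default 7).
#' @param order Polynomial order (default 5).
#' @param along \code{"wavelength"} (default) or \code{"temperature"}.
#' @return The smoothed \code{cd_series}.
#' @export
savitzky_golay_smooth <- function(series, window = 7, order = 5,
                                  along = c("wavelength", "temperature")) {
  stopifnot(inherits(series, "cd_series"))
  along <- match.arg(along)
  if (window %% 2 != 1 || window < order + 1)
    stopf("window must be odd and >= order + 1", class = "mabtherm_validation_error")
  n_axis <- if (along == "wavelength") length(series$wavelengths)
            else length(series$temperatures)
  if (window > n_axis)
    stopf("window (%d) exceeds the number of %s points (%d)",
          window, along, n_axis, class = "mabtherm_validation_error")
  out <- series
  if (along == "wavelength") {
    out$signal <- t(apply(series$signal, 1L, sg_smooth_vec, window = window,
                          order = order))
  } else {
    out$signal <- apply(series$signal, 2L, sg_smooth_vec, window = window,
                        order = order)
  }
  dimnames(out$signal) <- dimnames(series$signal)
  out
}

#' Convert millidegrees to mean residue ellipticity
#'
#' MRE(lambda, T) = theta_mdeg x MRW / (10 x pathlength_cm x conc_mg_per_mL),
#' with mean residue weight MRW = molecular_weight / (n_residues - 1).
#' Resulting units: deg cm^2 dmol^-1. The conversion is linear in theta, so
#' all downstream relative-fraction quantities are invariant to it.
#'
#' @param x A [cd_spectrum_series()] or [melt_signal()] in millidegrees.
#' @param meta A [sample_meta()]; defaults to the metadata carried by
#'   \code{x}.
#' @return \code{x} converted to MRE, with the units flag updated.
#' @export
to_mre <- function(x, meta = x$meta) {
  if (is.null(meta))
    stopf("sample metadata required for MRE conversion", class = "mabtherm_validation_error")
  stopifnot(inherits(meta, "sample_meta"))
  if (!identical(x$units, "millidegrees"))
    stopf("input is already in MRE; refusing to convert twice",
          class = "mabtherm_validation_error")
  mrw <- meta$molecular_weight / (meta$n_residues - 1)
  fac <- mrw / (10 * meta$pathlength * meta$protein_conc)
  out <- x
  if (inherits(x, "cd_series")) out$signal <- x$signal * fac
  else if (inherits(x, "melt_signal")) out$y <- x$y * fac
  else stopf("to_mre expects a cd_series or melt_signal")
  out$units <- "MRE"
  out$meta <- meta
  out
}

#' Run the full spectral preprocessing pipeline
#'
#' Applies, in a fixed order: background subtraction (if a background is
#' given), high-wavelength zeroing, Savitzky-Golay smoothing, and MRE
#' conversion (if the input is in millidegrees and metadata is available).
#' Re-running with the same inputs and configuration is bit-reproducible.
#'
#' @param series A [cd_spectrum_series()].
#' @param config A [preprocess_config()].
#' @param background Optional background (vector, matrix of replicates, or
#'   \code{cd_series}).
#' @return The preprocessed \code{cd_series}, with the applied steps recorded
#'   in \code{attr(, "preprocess_steps")}.
#' @export
preprocess_cd <- function(series, config = preprocess_config(),
                          background = NULL) {
  stopifnot(inherits(series, "cd_series"), inherits(config, "preprocess_config"))
  steps <- character(0)
  if (!is.null(background)) {
    if (is.matrix(background) || (is.list(background) && !inherits(background, "cd_series")))
      background <- average_background(background)
    series <- subtract_background(series, background)
    steps <- c(steps, "background")
  }
  series <- zero_high_wavelength(series, config$zero_window)
  steps <- c(steps, "zero")
  series <- savitzky_golay_smooth(series, config$sg_window, config$sg_order)
  steps <- c(steps, "sg_wavelength")
  if (config$smooth_temperature) {
    series <- savitzky_golay_smooth(series, config$sg_window, config$sg_order,
                                    along = "temperature")
    steps <- c(steps, "sg_temperature")
  }
  if (identical(series$units, "millidegrees") && !is.null(series$meta)) {
    series <- to_mre(series)
    steps <- c(steps, "mre")
  }
  attr(series, "preprocess_steps") <- steps
  series
}
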