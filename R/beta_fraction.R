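#' Relative beta-sheet fraction curve
#'
#' Constructor for the relative beta-sheet-fraction curve f(T). Users normally
#' obtain one from [fraction_two_state()], [fraction_peak_referenced()] or
#' [melt_fit()] rather than calling this directly.
#'
#' @param temperatures Temperatures, degrees C.
#' @param f Relative fraction values (dimensionless).
#' @param mode \code{"two_state"} or \code{"peak_referenced"}.
#' @param ref List describing the referencing used (baselines or constants).
#' @param scaled Logical: has the curve been affinely mapped onto [0, 1]?
#' @return An object of class \code{"beta_fraction"}.
#' @export
beta_fraction_curve <- function(temperatures, f,
                                mode = c("two_state", "peak_referenced"),
                                ref = NULL, scaled = FALSE) {
  mode <- match.arg(mode)
  temperatures <- as.numeric(temperatures); f <- as.numeric(f)
  if (length(temperatures) != length(f))
    stopf("temperatures and f must have equal length", class = "mabtherm_validation_error")
  if (!is_strictly_increasing(temperatures))
    stopf("temperatures must be strictly increasing", class = "mabtherm_validation_error")
  structure(list(temperatures = temperatures, f = f, mode = mode, ref = ref,
                 scaled = isTRUE(scaled)),
            class = "beta_fraction")
}

#' @export
print.beta_fraction <- function(x, ...) {
  cat(sprintf("Relative beta-sheet fraction curve (%s%s): %d points, f in [%.4g, %.4g]\n",
              x$mode, if (x$scaled) ", scaled" else "", length(x$f),
              min(x$f), max(x$f)))
  invisible(x)
}

#' Fit a linear pre- or post-transition baseline
#'
#' Ordinary least squares line y = a + b T restricted to a temperature
#' window; used for the extrapolated reference signals of the two-state
#' fraction (low-T baseline for the minimum-beta-sheet conformers, high-T
#' baseline for the maximum).
#'
#' @param signal A [melt_signal()] (or a [beta_fraction_curve()], whose f
#'   values are then fitted).
#' @param T_range Length-2 temperature interval, degrees C.
#' @param which \code{"low_T"} or \code{"high_T"}; a label recording which
#'   baseline this is.
#' @return An object of class \code{"baseline_fit"} with fields
#'   \code{intercept}, \code{slope}, \code{T_range}, \code{which},
#'   \code{r_squared}, \code{n}.
#' @export
fit_baseline <- function(signal, T_range, which = c("low_T", "high_T")) {
  which <- match.arg(which)
  tt <- signal$temperatures
  yy <- if (inherits(signal, "beta_fraction")) signal$f else signal$y
  if (length(T_range) != 2L || T_range[1] >= T_range[2])
    stopf("T_range must be an increasing length-2 interval",
          class = "mabtherm_validation_error")
  keep <- tt >= T_range[1] & tt <= T_range[2]
  if (sum(keep) < 3L)
    stopf("baseline fit needs >= 3 points in [%g, %g] degC (found %d)",
          T_range[1], T_range[2], sum(keep), class = "mabtherm_fit_error")
  fit <- stats::lm(yy[keep] ~ tt[keep])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((yy[keep] - mean(yy[keep]))^2)
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 T_range = as.numeric(T_range), which = which,
                 r_squared = if (tss > 0) 1 - rss / tss else 1,
                 n = sum(keep)),
            class = "baseline_fit")
}

## evaluate a baseline line (or a constant reference) at temperatures T
baseline_eval <- function(b, T) {
  if (is.numeric(b) && length(b) == 1L) rep(b, length(T))
  else b$intercept + b$slope * T
}

#' Two-state relative beta-sheet fraction
#'
#' Computes f(T) = (y(T) - y0(T)) / (ymax(T) - y0(T)), with y0 and ymax the
#' extrapolated low- and high-temperature baselines, so that f = 0 where the
#' signal sits on the minimum-beta-sheet baseline and f = 1 on the maximum.
#' Computed on the signed signal: at 218 nm more beta-sheet means more
#' negative MRE, and the referencing baselines carry the sign.
#'
#' @param signal A [melt_signal()].
#' @param low A \code{"low_T"} [fit_baseline()] result (y0).
#' @param high A \code{"high_T"} [fit_baseline()] result (ymax).
#' @param denom_floor_rel Relative floor on |ymax(T) - y0(T)|, as a fraction
#'   of the separation at the lowest measured temperature; guards against
#'   baseline crossover under extrapolation.
#' @return A [beta_fraction_curve()] in \code{"two_state"} mode (unscaled).
#' @export
fraction_two_state <- function(signal, low, high, denom_floor_rel = 1e-6) {
  stopifnot(inherits(signal, "melt_signal"))
  if (!identical(low$which, "low_T") || !identical(high$which, "high_T"))
    stopf("'low' must be a low_T baseline and 'high' a high_T baseline",
          class = "mabtherm_validation_error")
  tt <- signal$temperatures
  y0 <- baseline_eval(low, tt)
  ymax <- baseline_eval(high, tt)
  denom <- ymax - y0
  floor_abs <- denom_floor_rel * abs(denom[1L])
  bad <- which(abs(denom) <= floor_abs)
  if (length(bad))
    stopf("degenerate baseline separation |ymax - y0| <= %.3g at T = %g degC",
          floor_abs, tt[bad[1L]], class = "mabtherm_degenerate_error")
  f <- (signal$y - y0) / denom
  beta_fraction_curve(tt, f, mode = "two_state",
                      ref = list(low = low, high = high))
}

#' Peak-referenced relative beta-sheet fraction
#'
#' For melts whose beta-sheet content rises and then falls (non-monotone
#' 218 nm signal), f is computed with constant references: y0 is the
#' minimum-magnitude signal at the temperature endpoints and ymax the
#' strongest (most negative, for a negative band) signal over all
#' temperatures, so f = 1 at the internal extremum.
#'
#' @param signal A [melt_signal()].
#' @return A [beta_fraction_curve()] in \code{"peak_referenced"} mode.
#' @export
fraction_peak_referenced <- function(signal) {
  stopifnot(inherits(signal, "melt_signal"))
  y <- signal$y
  endpoints <- c(y[1L], y[length(y)])
  y0 <- endpoints[which.min(abs(endpoints))]
  ## strongest signal: largest magnitude over all T (most negative for the
  ## 218 nm band, where the signal is negative)
  ymax <- y[which.max(abs(y))]
  if (isTRUE(all.equal(y0, ymax)) || max(y) == min(y))
    stopf("degenerate signal: y0 equals ymax", class = "mabtherm_degenerate_error")
  f <- (y - y0) / (ymax - y0)
  beta_fraction_curve(signal$temperatures, f, mode = "peak_referenced",
                      ref = list(y0 = y0, ymax = ymax))
}

#' Rescale a fraction curve onto the unit interval
#'
#' Affine map sending [min f, max f] to [0, 1], so the conformers with
#' maximum beta-sheet content have f = 1 and those with minimum have f = 0.
#' Idempotent.
#'
#' @param curve A [beta_fraction_curve()].
#' @return The rescaled curve with \code{scaled = TRUE}.
#' @export
rescale_unit_interval <- function(curve) {
  stopifnot(inherits(curve, "beta_fraction"))
  lo <- min(curve$f); hi <- max(curve$f)
  if (hi <= lo)
    stopf("constant fraction curve cannot be rescaled", class = "mabtherm_degenerate_error")
  out <- curve
  out$f <- (curve$f - lo) / (hi - lo)
  out$scaled <- TRUE
  out
}

## Boltzmann sigmoid value: f(T) = A2 + (A1 - A2)/(1 + exp((T - T0)/dT))
boltzmann_eval <- function(T, A1, A2, T0, dT) {
  A2 + (A1 - A2) / (1 + exp((T - T0) / dT))
}

#' Choose the fraction-referencing mode for a melt signal
#'
#' Fits both a Boltzmann sigmoid and a bi-Gaussian to the raw y(T) and
#' selects \code{"peak_referenced"} when the bi-Gaussian has the lower RMSE
#' (minimum-RMSE model trialling) \emph{and} its fitted peak lies in the
#' interior of the temperature range -- a genuine rise-then-fall signal needs
#' an interior extremum, whereas for monotone data the best bi-Gaussian
#' pushes its centre to an end of the range. Otherwise \code{"two_state"}.
#'
#' @param signal A [melt_signal()].
#' @return \code{"two_state"} or \code{"peak_referenced"}.
#' @export
select_fraction_mode <- function(signal) {
  stopifnot(inherits(signal, "melt_signal"))
  tt <- signal$temperatures; yy <- signal$y
  rmse_sig <- tryCatch(fit_boltzmann(tt, yy)$rmse, error = function(e) Inf)
  big <- tryCatch(fit_bigaussian(tt, yy), error = function(e) NULL)
  if (is.infinite(rmse_sig) && is.null(big))
    stopf("neither a sigmoid nor a bi-Gaussian could be fitted to the signal",
          class = "mabtherm_fit_error")
  if (is.null(big)) return("two_state")
  margin <- 0.05 * diff(range(tt))
  interior_peak <- big$params$Tc > min(tt) + margin &&
                   big$params$Tc < max(tt) - margin
  if (big$rmse < rmse_sig && interior_peak) "peak_referenced" else "two_state"
}
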