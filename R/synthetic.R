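#' Specification of one two-state thermal transition
#'
#' Forward-model parameters of a single van't Hoff transition: midpoint
#' temperature, van't Hoff enthalpy, and the fraction levels the transition
#' connects.
#'
#' @param T_m Midpoint temperature, degC.
#' @param dH_vH Van't Hoff enthalpy, J/mol (> 0).
#' @param f_start,f_end Fraction levels bracketing the transition, in [0, 1].
#' @return An object of class \code{"transition_spec"}. Note the implied
#'   Celsius-convention entropy: dS = dH_vH / T_m(K).
#' @export
transition_spec <- function(T_m, dH_vH, f_start = 0, f_end = 1) {
  check_number(T_m, "T_m")
  check_number(dH_vH, "dH_vH", positive = TRUE)
  if (f_start < 0 || f_start > 1 || f_end < 0 || f_end > 1)
    stopf("f_start and f_end must lie in [0, 1]", class = "mabtherm_validation_error")
  structure(list(T_m = T_m, dH_vH = dH_vH, f_start = f_start, f_end = f_end),
            class = "transition_spec")
}

#' Specification of a synthetic melt curve
#'
#' One to three sequential two-state transitions riding on linear pre- and
#' post-transition baselines, sampled on a temperature grid with optional
#' homoscedastic Gaussian noise.
#'
#' @param transitions List of [transition_spec()], ordered by \code{T_m}.
#' @param baseline_low,baseline_high Length-2 \code{c(intercept, slope)} of
#'   the minimum- and maximum-beta-sheet baselines y0(T), ymax(T) in signal
#'   units (MRE-like by default: negative 218 nm band).
#' @param T_grid Temperature grid, degC (default 25-97 degC in 1 degC steps,
#'   the standard variable-temperature CD ramp).
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param seed Integer seed used when noise is drawn.
#' @return An object of class \code{"melt_spec"}.
#' @export
melt_spec <- function(transitions, baseline_low = c(-3000, 2),
                      baseline_high = c(-6500, 4),
                      T_grid = seq(25, 97, by = 1), noise_sd = 0,
                      seed = NULL) {
  if (inherits(transitions, "transition_spec")) transitions <- list(transitions)
  if (!length(transitions) || !all(vapply(transitions, inherits, logical(1), "transition_spec")))
    stopf("'transitions' must be a list of transition_spec objects",
          class = "mabtherm_validation_error")
  tm <- vapply(transitions, `[[`, numeric(1), "T_m")
  if (is.unsorted(tm, strictly = TRUE))
    stopf("transitions must be strictly ordered by T_m", class = "mabtherm_validation_error")
  if (!is_strictly_increasing(T_grid))
    stopf("T_grid must be strictly increasing", class = "mabtherm_validation_error")
  structure(list(transitions = transitions,
                 baseline_low = as.numeric(baseline_low),
                 baseline_high = as.numeric(baseline_high),
                 T_grid = as.numeric(T_grid), noise_sd = noise_sd,
                 seed = seed),
            class = "melt_spec")
}

#' Named melt-curve presets
#'
#' \code{"f1il-like"}: the hardest case emulated by the generator -- three
#' sequential transitions (rise, rise, fall) with midpoints 52.4, 67.5 and
#' 86.8 degC and van't Hoff enthalpies chosen so the Celsius-convention
#' entropies are 910, 2200 and 960 J/(K mol). \code{"f1-like"}: a single
#' transition at 77.0 degC with dS = 1560 J/(K mol). \code{"water-like"}:
#' two transitions (75.5 and 91.8 degC; dS 1230 and 3090 J/(K mol)), the
#' second falling. Default noise is 1% of the mean baseline separation;
#' pass \code{noise_sd = 0} for noiseless curves.
#'
#' @param name Preset name.
#' @param noise_sd Noise SD in signal units; \code{NULL} for the 1%-of-span
#'   default.
#' @param seed Integer seed.
#' @return A [melt_spec()].
#' @export
melt_preset <- function(name = c("f1il-like", "f1-like", "water-like"),
                        noise_sd = NULL, seed = NULL) {
  name <- match.arg(name)
  dH_from_dS <- function(dS, T_m) dS * celsius_to_kelvin(T_m)
  trs <- switch(name,
    "f1il-like" = list(
      transition_spec(52.4, dH_from_dS(910, 52.4), 0, 0.45),
      transition_spec(67.5, dH_from_dS(2200, 67.5), 0.45, 1),
      transition_spec(86.8, dH_from_dS(960, 86.8), 1, 0.4)),
    "f1-like" = list(
      transition_spec(77.0, dH_from_dS(1560, 77.0), 0, 1)),
    "water-like" = list(
      transition_spec(75.5, dH_from_dS(1230, 75.5), 0, 0.75),
      transition_spec(91.83, dH_from_dS(3090, 91.83), 0.75, 0.1)))
  spec <- melt_spec(trs, seed = seed)
  if (is.null(noise_sd)) {
    sep <- abs(mean(spec$baseline_high[1] + spec$baseline_high[2] * spec$T_grid -
                    spec$baseline_low[1] - spec$baseline_low[2] * spec$T_grid))
    noise_sd <- 0.01 * sep
  }
  spec$noise_sd <- noise_sd
  spec
}

#' Generate the noiseless true fraction curve of a melt specification
#'
#' f(T) = f_start1 + sum_i (f_end_i - f_start_i) p_i(T), where each
#' p_i = K_i / (1 + K_i) and K_i = exp(-(dH_vH_i/R) (1/T_K - 1/T_m_i(K))) is
#' the van't Hoff equilibrium occupancy of transition i (p_i = 0.5 exactly at
#' T_m_i). Deterministic; opposing transitions produce rise-fall curves and a
#' warning is emitted if f leaves [0, 1].
#'
#' @param spec A [melt_spec()].
#' @return A data frame with columns \code{T} and \code{f_true}.
#' @export
generate_fraction_curve <- function(spec) {
  stopifnot(inherits(spec, "melt_spec"))
  TK <- celsius_to_kelvin(spec$T_grid)
  f <- rep(spec$transitions[[1L]]$f_start, length(TK))
  for (tr in spec$transitions) {
    K <- exp(-(tr$dH_vH / .R_GAS) * (1 / TK - 1 / celsius_to_kelvin(tr$T_m)))
    f <- f + (tr$f_end - tr$f_start) * K / (1 + K)
  }
  if (any(f < -1e-9 | f > 1 + 1e-9))
    warnf("true fraction leaves [0, 1] (range %.3g to %.3g): overlapping transitions",
          min(f), max(f))
  data.frame(T = spec$T_grid, f_true = f)
}

#' Generate a synthetic single-wavelength CD melt signal
#'
#' Inverse of the two-state referencing: y(T) = y0(T) + (ymax(T) - y0(T))
#' f_true(T) + noise, with y0/ymax the specification's linear baselines and
#' seeded Gaussian noise. The generating truth (spec and f_true) is attached
#' as \code{attr(, "truth")}.
#'
#' @param spec A [melt_spec()].
#' @param f_true Optional precomputed [generate_fraction_curve()] output.
#' @return A [melt_signal()] at 218 nm (MRE units).
#' @export
generate_cd_signal <- function(spec, f_true = NULL) {
  stopifnot(inherits(spec, "melt_spec"))
  if (is.null(f_true)) f_true <- generate_fraction_curve(spec)
  tt <- spec$T_grid
  y0 <- spec$baseline_low[1] + spec$baseline_low[2] * tt
  ymax <- spec$baseline_high[1] + spec$baseline_high[2] * tt
  if (any(sign(ymax - y0) != sign(ymax[1] - y0[1])) || any(ymax == y0))
    stopf("baselines cross within the temperature grid", class = "mabtherm_validation_error")
  y <- y0 + (ymax - y0) * f_true$f_true
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
  }
  sig <- melt_signal(tt, y, wavelength = 218, units = "MRE")
  attr(sig, "truth") <- list(spec = spec, f_true = f_true$f_true)
  sig
}

#' Spectral band basis for full synthetic CD spectra
#'
#' Gaussian bands emulating the far-UV CD of a beta-sheet-rich antibody:
#' a strong negative band at 218 nm (beta-sheet) and a positive band at
#' 202 nm (beta-turn).
#'
#' @param bands Data frame with columns \code{centre} (nm), \code{width}
#'   (nm, > 0), \code{rel_amp} (amplitude relative to the 218 nm band;
#'   signs included).
#' @return An object of class \code{"spectrum_basis"}.
#' @export
spectrum_basis <- function(bands = data.frame(centre = c(218, 202),
                                              width = c(9, 5),
                                              rel_amp = c(1, -0.45))) {
  if (any(bands$width <= 0))
    stopf("band widths must be > 0", class = "mabtherm_validation_error")
  structure(list(bands = bands), class = "spectrum_basis")
}

#' Generate a full synthetic temperature-resolved CD spectrum series
#'
#' Builds spectra as sums of Gaussian bands whose 218 nm-band amplitude is
#' driven by the true fraction through the same baseline map as
#' [generate_cd_signal()]; the amplitudes are normalised so that, at zero
#' noise, extracting the 218 nm column reproduces the single-wavelength
#' signal exactly.
#'
#' @param spec A [melt_spec()].
#' @param basis A [spectrum_basis()].
#' @param wavelengths Wavelength grid, nm (default 190-260, 1 nm).
#' @return A [cd_spectrum_series()] in MRE units, truth attached as for
#'   [generate_cd_signal()].
#' @export
generate_full_spectra <- function(spec, basis = spectrum_basis(),
                                  wavelengths = 190:260) {
  stopifnot(inherits(spec, "melt_spec"), inherits(basis, "spectrum_basis"))
  noiseless <- spec; noiseless$noise_sd <- 0
  sig <- generate_cd_signal(noiseless)
  bands <- basis$bands
  i218 <- which.min(abs(bands$centre - 218))
  g <- function(centre, width) exp(-(wavelengths - centre)^2 / (2 * width^2))
  ## cross-talk of the other bands at 218 nm, per unit 218-band amplitude
  other <- setdiff(seq_len(nrow(bands)), i218)
  at218 <- function(centre, width) exp(-(218 - centre)^2 / (2 * width^2))
  cross <- sum(bands$rel_amp[other] *
                 mapply(at218, bands$centre[other], bands$width[other]))
  amp218 <- sig$y / (1 + cross)     # so the summed spectrum at 218 equals y
  S <- matrix(0, length(sig$temperatures), length(wavelengths))
  for (b in seq_len(nrow(bands)))
    S <- S + outer(amp218 * bands$rel_amp[b], g(bands$centre[b], bands$width[b]))
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    S <- S + stats::rnorm(length(S), 0, spec$noise_sd)
  }
  ser <- cd_spectrum_series(sig$temperatures, wavelengths, S, units = "MRE")
  attr(ser, "truth") <- attr(sig, "truth")
  ser
}

#' Generate a noisy BLI sensorgram with known kinetics
#'
#' Simulates a 1:1 or 1:2 sensorgram ([simulate_1to1()]/[simulate_1to2()])
#' and adds seeded Gaussian noise and an optional linear baseline drift.
#'
#' @param params Named list of kinetic constants: \code{kon, koff, Rmax} for
#'   1:1 or \code{kon1, koff1, Rmax1, kon2, koff2, Rmax2} for 1:2.
#' @param C Analyte concentration, M.
#' @param model \code{"one_to_one"} or \code{"one_to_two"}.
#' @param model_form Passed to [simulate_1to2()].
#' @param noise_sd Gaussian noise SD, nm.
#' @param drift Linear drift, nm/s.
#' @param seed Integer seed.
#' @param ... Phase durations / sampling passed to the simulator.
#' @return A [sensorgram()] with the generating truth attached as
#'   \code{attr(, "truth")}.
#' @export
generate_sensorgram <- function(params, C, model = c("one_to_two", "one_to_one"),
                                model_form = "parallel_sites",
                                noise_sd = 0, drift = 0, seed = NULL, ...) {
  model <- match.arg(model)
  sg <- if (model == "one_to_one")
    simulate_1to1(params$kon, params$koff, params$Rmax, C, ...)
  else
    simulate_1to2(params$kon1, params$koff1, params$Rmax1,
                  params$kon2, params$koff2, params$Rmax2, C,
                  model_form = model_form, ...)
  if (noise_sd > 0 || drift != 0) {
    if (!is.null(seed)) set.seed(seed)
    sg$R <- sg$R + drift * sg$t +
      if (noise_sd > 0) stats::rnorm(length(sg$t), 0, noise_sd) else 0
  }
  attr(sg, "truth") <- list(params = params, C = C, model = model,
                            model_form = model_form, noise_sd = noise_sd,
                            drift = drift, seed = seed)
  sg
}
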