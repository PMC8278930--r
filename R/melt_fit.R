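#' Control parameters for melt-curve analysis
#'
#' @param min_plateau_points Minimum plateau size, points.
#' @param slope_tol Maximum plateau |slope|, fraction units per degC.
#' @param r2_floor r-squared floor for the single-line plateau fallback.
#' @param onset_mode Onset construction: \code{"tangent"} or
#'   \code{"threshold"} (see [onset_temperature()]).
#' @param onset_threshold Amplitude fraction for threshold-mode onset.
#' @param dG_window Half-width of the |Delta G| transition window, kJ/mol.
#' @param epsilon_f Margin excluding f near 0/1 before ln K.
#' @param convention Which enthalpy leads in reports: \code{"paper"}
#'   (Celsius-axis intercept) or \code{"vanthoff"} (T_m(K) x dS). Both are
#'   always computed from the same regression.
#' @param T_ref_rule Reference temperature rule for the total Gibbs energy:
#'   \code{"last_intersection"} (default) or \code{"last_T_m"}.
#' @param baseline_refine Logical: after a first two-state pass, re-fit the
#'   low/high baselines on data at least 8 sigmoid widths away from the
#'   outermost midpoints (shrinking to 4 widths if too few points remain)
#'   and re-segment. Removes the transition-tail contamination of
#'   automatically detected baseline windows.
#' @param region_refs Region reference signals for the per-region fraction:
#'   \code{"model"} (default; boundary lines implied by a joint van't Hoff
#'   staircase refit of the whole curve), \code{"plateau"} (lines fitted to
#'   bounding plateaus, sigmoid asymptotes where a bounding plateau is
#'   missing or too short) or \code{"sigmoid"} (asymptote constants only).
#' @param denom_floor_rel Relative floor guarding degenerate baseline
#'   separations.
#' @return A list of class \code{"melt_control"}.
#' @export
melt_control <- function(min_plateau_points = 5L, slope_tol = 0.02,
                         r2_floor = 0.98,
                         onset_mode = c("tangent", "threshold"),
                         onset_threshold = 0.05, dG_window = 5,
                         epsilon_f = 0.02,
                         convention = c("paper", "vanthoff"),
                         T_ref_rule = c("last_intersection", "last_T_m"),
                         baseline_refine = TRUE,
                         region_refs = c("model", "plateau", "sigmoid"),
                         denom_floor_rel = 1e-6) {
  structure(list(min_plateau_points = as.integer(min_plateau_points),
                 slope_tol = slope_tol, r2_floor = r2_floor,
                 onset_mode = match.arg(onset_mode),
                 onset_threshold = onset_threshold,
                 dG_window = dG_window, epsilon_f = epsilon_f,
                 convention = match.arg(convention),
                 T_ref_rule = match.arg(T_ref_rule),
                 baseline_refine = isTRUE(baseline_refine),
                 region_refs = match.arg(region_refs),
                 denom_floor_rel = denom_floor_rel),
            class = "melt_control")
}

## find the plateaus bounding a sigmoid's midpoint (below / above T0)
bounding_plateaus <- function(plateaus, T0) {
  below <- Filter(function(p) mean(p$T_range) < T0, plateaus)
  above <- Filter(function(p) mean(p$T_range) > T0, plateaus)
  list(low = if (length(below)) below[[length(below)]] else NULL,
       high = if (length(above)) above[[1L]] else NULL)
}

#' Fit the full melt-curve model
#'
#' The package's central fitting function. Takes a single-wavelength melt
#' signal (or a precomputed fraction curve), derives the relative
#' beta-sheet-fraction curve, segments it into linear plateaus and Boltzmann
#' sigmoid transition regions, selects the overall guide-shape model by
#' minimum RMSE, and computes midpoint temperatures T_m, intersection
#' temperatures T_I, the onset temperature, per-region two-state
#' thermodynamics (K, Delta G, Delta H, Delta S) and their totals.
#'
#' @param x A [melt_signal()] (typically the 218 nm series), a
#'   [cd_spectrum_series()] (the 218 nm column is extracted), or a
#'   [beta_fraction_curve()].
#' @param mode Fraction referencing mode: \code{"auto"} (minimum-RMSE
#'   choice between a sigmoid and a bi-Gaussian description of the raw
#'   signal), \code{"two_state"} or \code{"peak_referenced"}. Ignored when
#'   \code{x} is already a fraction curve.
#' @param baseline_low,baseline_high Optional length-2 temperature windows
#'   (degC) for the two-state baseline fits; default: the first/last
#'   detected plateau of the raw signal.
#' @param control A [melt_control()].
#' @param wavelength Wavelength extracted when \code{x} is a spectrum series.
#' @return An object of class \code{"melt_fit"}; see
#'   [summary.melt_fit()], [coef.melt_fit()], [predict.melt_fit()],
#'   [plot.melt_fit()].
#' @examples
#' spec <- melt_spec(transitions = list(transition_spec(77, 4.3e5)),
#'                   noise_sd = 0, seed = 1)
#' sig <- generate_cd_signal(spec)
#' fit <- melt_fit(sig)
#' coef(fit)["T_m1"]
#' @export
melt_fit <- function(x, mode = c("auto", "two_state", "peak_referenced"),
                     baseline_low = NULL, baseline_high = NULL,
                     control = melt_control(), wavelength = 218) {
  mode <- match.arg(mode)
  stopifnot(inherits(control, "melt_control"))
  cl <- match.call()
  if (inherits(x, "cd_series")) x <- extract_wavelength(x, wavelength)

  baselines <- NULL
  if (inherits(x, "beta_fraction")) {
    signal <- NULL
    curve <- x
    mode <- x$mode
  } else if (inherits(x, "melt_signal")) {
    signal <- x
    if (mode == "auto") mode <- select_fraction_mode(signal)
    if (mode == "two_state") {
      if (is.null(baseline_low) || is.null(baseline_high)) {
        ## detect tail plateaus on the range-normalised raw signal so
        ## slope_tol keeps its fraction-units meaning
        rng <- range(signal$y)
        norm <- beta_fraction_curve(signal$temperatures,
                                    (signal$y - rng[1]) / diff(rng),
                                    mode = "two_state")
        pl <- detect_plateaus(norm, control$min_plateau_points,
                              control$slope_tol, control$r2_floor)
        if (length(pl) < 2L)
          stopf("could not locate both tail plateaus for baseline fitting; supply baseline_low/baseline_high",
                class = "mabtherm_segmentation_error")
        if (is.null(baseline_low)) baseline_low <- pl[[1L]]$T_range
        if (is.null(baseline_high)) baseline_high <- pl[[length(pl)]]$T_range
      }
      b_lo <- if (inherits(baseline_low, "baseline_fit")) baseline_low
              else fit_baseline(signal, baseline_low, "low_T")
      b_hi <- if (inherits(baseline_high, "baseline_fit")) baseline_high
              else fit_baseline(signal, baseline_high, "high_T")
      baselines <- list(low = b_lo, high = b_hi)
      curve <- fraction_two_state(signal, b_lo, b_hi,
                                  denom_floor_rel = control$denom_floor_rel)
    } else {
      curve <- fraction_peak_referenced(signal)
    }
  } else stopf("x must be a melt_signal, cd_series or beta_fraction curve")

  segment <- function(curve) {
    curve <- rescale_unit_interval(curve)
    plateaus <- detect_plateaus(curve, control$min_plateau_points,
                                control$slope_tol, control$r2_floor)
    shape <- tryCatch(fit_shape_models(curve), error = function(e) NULL)
    sigmoids <- fit_sigmoid_chain(curve, plateaus, shape)
    list(curve = curve, plateaus = plateaus, shape = shape,
         sigmoids = sigmoids)
  }
  seg <- segment(curve)

  ## refinement pass: re-fit the two-state baselines on data clear of the
  ## outermost transitions (tail contamination biases automatic windows)
  if (mode == "two_state" && control$baseline_refine && !is.null(signal)) {
    s1 <- seg$sigmoids[[1L]]
    sl <- seg$sigmoids[[length(seg$sigmoids)]]
    tt <- signal$temperatures
    refined <- tryCatch({
      pick_window <- function(side) {
        for (k in c(8, 6, 4)) {
          keep <- if (side == "low") tt <= s1$T0 - k * s1$dT
                  else tt >= sl$T0 + k * sl$dT
          if (sum(keep) >= max(3L, control$min_plateau_points))
            return(range(tt[keep]))
        }
        NULL
      }
      wlo <- pick_window("low"); whi <- pick_window("high")
      if (is.null(wlo) || is.null(whi)) NULL
      else {
        b_lo <- fit_baseline(signal, wlo, "low_T")
        b_hi <- fit_baseline(signal, whi, "high_T")
        list(baselines = list(low = b_lo, high = b_hi),
             seg = segment(fraction_two_state(
               signal, b_lo, b_hi,
               denom_floor_rel = control$denom_floor_rel)))
      }
    }, error = function(e) NULL)
    if (!is.null(refined)) {
      baselines <- refined$baselines
      seg <- refined$seg
    }
  }

  curve <- seg$curve; plateaus <- seg$plateaus
  shape <- seg$shape; sigmoids <- seg$sigmoids
  r <- length(sigmoids)
  T_m <- vapply(sigmoids, `[[`, numeric(1), "T0")

  ## intersections come from the independent span fits: the refined chain
  ## shares exact plateau levels, so adjacent refined sigmoids are tangent,
  ## not crossing
  span_fits <- attr(sigmoids, "span_fits") %||% sigmoids
  T_I <- numeric(0)
  if (r >= 2L)
    T_I <- vapply(seq_len(r - 1L), function(i)
      intersection_temperature(span_fits[[i]], span_fits[[i + 1L]]), numeric(1))

  T_onset <- tryCatch(
    onset_temperature(curve, sigmoids[[1L]], plateaus[[1L]],
                      mode = control$onset_mode,
                      threshold = control$onset_threshold),
    error = function(e) { warnf("onset undefined: %s", conditionMessage(e)); NA_real_ })

  vh <- if (control$region_refs == "model")
    fit_vh_staircase(curve$temperatures, curve$f, sigmoids) else NULL
  regions <- vector("list", r)
  for (i in seq_len(r)) {
    lo_ref <- hi_ref <- NULL
    if (control$region_refs == "plateau") {
      bp <- bounding_plateaus(plateaus, sigmoids[[i]]$T0)
      if (!is.null(bp$low) && bp$low$n_points >= 3L) lo_ref <- bp$low
      if (!is.null(bp$high) && bp$high$n_points >= 3L) hi_ref <- bp$high
    } else if (!is.null(vh)) {
      lo_ref <- vh$refs[[i]]; hi_ref <- vh$refs[[i + 1L]]
    }
    regions[[i]] <- region_thermo(curve, sigmoids[[i]], lo_ref, hi_ref,
                                  index = i, epsilon_f = control$epsilon_f,
                                  dG_window = control$dG_window)
  }
  tot <- totals(regions,
                T_ref = if (control$T_ref_rule == "last_T_m")
                          T_m[r] else NULL,
                T_I = T_I)

  structure(list(signal = signal, curve = curve, mode = curve$mode,
                 baselines = baselines, plateaus = plateaus,
                 sigmoids = sigmoids, shape = shape,
                 T_m = T_m, T_I = T_I, T_onset = T_onset,
                 regions = regions, totals = tot,
                 control = control, n = length(curve$f), call = cl),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Melt-curve fit (", x$mode, " referencing)\n", sep = "")
  cat(sprintf("  %d points, %d plateau(s), %d sigmoid region(s)\n",
              x$n, length(x$plateaus), length(x$sigmoids)))
  cat("  T_m:", paste(sprintf("%.1f", x$T_m), collapse = ", "), "degC")
  if (length(x$T_I))
    cat(";  T_I:", paste(sprintf("%.1f", x$T_I), collapse = ", "), "degC")
  cat(sprintf(";  T_onset: %s degC\n",
              if (is.na(x$T_onset)) "NA" else sprintf("%.1f", x$T_onset)))
  print(x$totals)
  invisible(x)
}

#' Summarise a melt-curve fit
#'
#' @param object A \code{"melt_fit"}.
#' @param ... Unused.
#' @return A \code{"summary.melt_fit"}: per-region table (T_m, dH, dS and
#'   standard errors), intersection/onset temperatures and totals.
#' @export
summary.melt_fit <- function(object, ...) {
  reg <- do.call(rbind, lapply(object$regions, function(r)
    data.frame(region = r$index, T_m = r$T_m, dH_kJ_mol = r$dH_paper,
               dS_J_K_mol = r$dS, dH_vH_kJ_mol = r$dH_vH,
               se_T_m = r$se[["T_m"]], se_dH = r$se[["dH_paper"]],
               se_dS = r$se[["dS"]], n = r$n)))
  structure(list(mode = object$mode, n = object$n,
                 shape = if (is.null(object$shape)) NA_character_
                         else object$shape$kind,
                 regions = reg, T_I = object$T_I, T_onset = object$T_onset,
                 totals = object$totals, convention = object$control$convention),
            class = "summary.melt_fit")
}

#' @export
print.summary.melt_fit <- function(x, ...) {
  cat("Melt-curve analysis (", x$mode, " referencing, shape: ", x$shape,
      ")\n\n", sep = "")
  cat("Per-region thermodynamics (",
      if (x$convention == "paper") "Celsius-axis dH convention"
      else "van't Hoff dH convention", "):\n", sep = "")
  print(x$regions, row.names = FALSE, digits = 4)
  cat("\nT_onset:", if (is.na(x$T_onset)) "NA" else sprintf("%.1f degC", x$T_onset))
  if (length(x$T_I))
    cat(";  T_I:", paste(sprintf("%.1f", x$T_I), collapse = ", "), "degC")
  cat("\n\n")
  print(x$totals)
  invisible(x)
}

#' Extract coefficients of a melt-curve fit
#'
#' @param object A \code{"melt_fit"}.
#' @param ... Unused.
#' @return Named numeric vector: \code{T_onset}, \code{T_m<i>},
#'   \code{T_I<i>}, per-region \code{dH<i>}/\code{dS<i>} and the totals.
#' @export
coef.melt_fit <- function(object, ...) {
  r <- length(object$sigmoids)
  out <- c(T_onset = object$T_onset)
  out[paste0("T_m", seq_len(r))] <- object$T_m
  if (length(object$T_I)) out[paste0("T_I", seq_along(object$T_I))] <- object$T_I
  for (i in seq_len(r)) {
    out[paste0("dH", i)] <- object$regions[[i]]$dH_paper
    out[paste0("dS", i)] <- object$regions[[i]]$dS
  }
  out["dH_total"] <- object$totals$dH_total
  out["dS_total"] <- object$totals$dS_total
  out["dG_total"] <- object$totals$dG_total
  out
}

## piecewise prediction: each temperature is predicted from the sigmoid
## whose fit span covers it (nearest midpoint wins on overlaps)
predict_chain <- function(sigmoids, T) {
  r <- length(sigmoids)
  T0s <- vapply(sigmoids, `[[`, numeric(1), "T0")
  out <- numeric(length(T))
  for (k in seq_along(T)) {
    covers <- which(vapply(sigmoids, function(s)
      T[k] >= s$fit_T_range[1L] && T[k] <= s$fit_T_range[2L], logical(1)))
    i <- if (length(covers)) covers[which.min(abs(T0s[covers] - T[k]))]
         else which.min(pmin(abs(T[k] - vapply(sigmoids, function(s) s$fit_T_range[1L], numeric(1))),
                             abs(T[k] - vapply(sigmoids, function(s) s$fit_T_range[2L], numeric(1)))))
    s <- sigmoids[[i]]
    out[k] <- boltzmann_eval(T[k], s$A1, s$A2, s$T0, s$dT)
  }
  out
}

#' Predict the fraction curve from a melt-curve fit
#'
#' @param object A \code{"melt_fit"}.
#' @param newdata Temperatures (numeric vector or data frame with column
#'   \code{T}); default: the fitted temperatures.
#' @param ... Unused.
#' @return Predicted relative beta-sheet fraction at \code{newdata}.
#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$curve$temperatures
       else if (is.data.frame(newdata)) newdata$T
       else as.numeric(newdata)
  predict_chain(object$sigmoids, T)
}

#' @export
fitted.melt_fit <- function(object, ...) predict(object)

#' @export
residuals.melt_fit <- function(object, ...) object$curve$f - predict(object)

#' Simulate fraction curves from a fitted melt model
#'
#' Draws Gaussian noise with the fit's residual standard deviation around the
#' fitted piecewise-sigmoid curve.
#'
#' @param object A \code{"melt_fit"}.
#' @param nsim Number of simulated curves.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A matrix, one column per simulation, rows matching the fitted
#'   temperatures.
#' @export
simulate.melt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sd <- stats::sd(residuals(object))
  matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sd),
         ncol = nsim,
         dimnames = list(NULL, paste0("sim_", seq_len(nsim))))
}

#' Plot a melt-curve fit
#'
#' Fraction data with the fitted sigmoid chain, the guide shape model and
#' vertical markers at T_m (dashed) and T_I (dotted).
#'
#' @param x A \code{"melt_fit"}.
#' @param ... Passed to \code{plot()}.
#' @export
plot.melt_fit <- function(x, ...) {
  tt <- x$curve$temperatures
  graphics::plot(tt, x$curve$f, xlab = "Temperature (degC)",
                 ylab = "Relative beta-sheet fraction", pch = 16,
                 col = "grey40", ...)
  for (i in seq_along(x$sigmoids)) {
    s <- x$sigmoids[[i]]
    tg <- seq(s$fit_T_range[1L], s$fit_T_range[2L], length.out = 100)
    graphics::lines(tg, boltzmann_eval(tg, s$A1, s$A2, s$T0, s$dT),
                    col = i + 1L, lwd = 2)
  }
  if (!is.null(x$shape)) {
    tg <- seq(min(tt), max(tt), length.out = 200)
    graphics::lines(tg, shape_eval(x$shape, tg), lty = 3, col = "grey30")
  }
  graphics::abline(v = x$T_m, lty = 2, col = "grey55")
  if (length(x$T_I)) graphics::abline(v = x$T_I, lty = 3, col = "grey70")
  invisible(x)
}
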