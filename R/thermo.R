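#' Region-local fraction of the final conformation
#'
#' For transition region i, computes f_i(T) = (y - y0_i(T)) / (ymax_i(T) -
#' y0_i(T)), where y0_i and ymax_i are the reference signals of the initial
#' and final conformations within the region: lines fitted to the bounding
#' plateaus where available, else the sigmoid's own asymptotes A1/A2 as
#' constants. f_i runs from 0 at the region start to 1 at the region end
#' whatever the direction of the underlying signal change.
#'
#' @param curve A [beta_fraction_curve()] (or [melt_signal()]).
#' @param sigmoid The region's \code{"boltzmann_fit"}.
#' @param low_ref,high_ref Reference for the region start/end: a
#'   \code{"plateau"}, a \code{"baseline_fit"}, a single number (constant),
#'   or \code{NULL} to fall back to the sigmoid's A1/A2.
#' @param denom_floor_rel Relative floor on the reference separation.
#' @return A data frame with columns \code{T} (degC, restricted to the
#'   sigmoid's fit range) and \code{f_i}.
#' @export
region_fraction <- function(curve, sigmoid, low_ref = NULL, high_ref = NULL,
                            denom_floor_rel = 1e-6) {
  tv <- get_tv(curve)
  keep <- tv$t >= sigmoid$fit_T_range[1L] & tv$t <= sigmoid$fit_T_range[2L]
  tt <- tv$t[keep]; yy <- tv$v[keep]
  as_line <- function(ref, const) {
    if (is.null(ref)) const
    else if (inherits(ref, c("plateau", "baseline_fit")) || is.list(ref)) ref
    else as.numeric(ref)
  }
  lo <- as_line(low_ref, sigmoid$A1)
  hi <- as_line(high_ref, sigmoid$A2)
  y0 <- baseline_eval(lo, tt)
  ymax <- baseline_eval(hi, tt)
  denom <- ymax - y0
  floor_abs <- denom_floor_rel * max(abs(denom))
  if (any(abs(denom) <= floor_abs) || all(denom == 0))
    stopf("degenerate region references: |ymax_i - y0_i| vanishes at T = %g degC",
          tt[which(abs(denom) <= floor_abs)[1L]], class = "mabtherm_degenerate_error")
  data.frame(T = tt, f_i = (yy - y0) / denom)
}

#' Two-state equilibrium constant from a fraction
#'
#' K = f / (1 - f): the ratio of protein in the final over the initial
#' conformation of a two-state transition. Defined only on 0 < f < 1;
#' out-of-range points are a domain error (callers exclude them from
#' downstream fits rather than clamping).
#'
#' @param f Fraction(s) in (0, 1).
#' @return K, same length as \code{f}.
#' @examples
#' equilibrium_constant(0.5)   # 1
#' equilibrium_constant(0.75)  # 3
#' @export
equilibrium_constant <- function(f) {
  if (any(f <= 0 | f >= 1))
    stopf("equilibrium constant requires 0 < f < 1 (got %g)",
          f[which(f <= 0 | f >= 1)[1L]], class = "mabtherm_domain_error")
  f / (1 - f)
}

#' Gibbs free energy of transition
#'
#' Delta G = -R T ln K with R = 8.314 J/(mol K) and T converted from degrees
#' C to Kelvin; returned in kJ/mol.
#'
#' @param K Equilibrium constant(s), > 0.
#' @param T_celsius Temperature(s), degrees C.
#' @return Delta G in kJ/mol.
#' @examples
#' gibbs(1, 25)       # 0
#' gibbs(exp(1), 25)  # -2.479 kJ/mol
#' @export
gibbs <- function(K, T_celsius) {
  if (any(K <= 0))
    stopf("K must be > 0", class = "mabtherm_domain_error")
  -.R_GAS * celsius_to_kelvin(T_celsius) * log(K) / 1000
}

#' Linear fit of the Gibbs energy in the transition window
#'
#' Fits Delta G = dH - T dS by least squares against temperature on the
#' Celsius axis, restricted to the transition window |Delta G| < window
#' (default 5 kJ/mol). The line's root gives the midpoint temperature
#' T_m = dH/dS (degC). Under this Celsius-axis convention the reported
#' enthalpy is the intercept at 0 degC and satisfies dH = T_m(degC) x dS
#' identically; the van't Hoff enthalpy dH_vH = T_m(K) x dS is reported
#' alongside. Standard errors come from the unweighted fit covariance.
#'
#' @param T_celsius,dG Numeric vectors: temperature (degC) and Gibbs energy
#'   (kJ/mol).
#' @param window Half-width of the |Delta G| window, kJ/mol.
#' @return A list with \code{T_m} (degC), \code{dS} (J/(K mol)),
#'   \code{dH_paper} (kJ/mol, Celsius-axis intercept), \code{dH_vH}
#'   (kJ/mol), standard errors \code{se} (T_m, dS, dH), \code{n} points
#'   used, and the underlying \code{lm} fit.
#' @export
linear_transition_fit <- function(T_celsius, dG, window = 5) {
  keep <- which(is.finite(dG) & abs(dG) < window)
  if (length(keep) >= 3L) {
    ## only the contiguous in-window run around the dG zero crossing:
    ## a neighbouring transition can bring |dG| back under the window far
    ## from this region's midpoint
    runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
    anchor <- keep[which.min(abs(dG[keep]))]
    keep <- runs[[which(vapply(runs, function(r) anchor %in% r, logical(1)))]]
  }
  if (length(keep) < 3L)
    stopf("need >= 3 points with |dG| < %g kJ/mol (found %d)", window,
          length(keep), class = "mabtherm_fit_error")
  tt <- T_celsius[keep]; gg <- dG[keep]
  fit <- stats::lm(gg ~ tt)
  cf <- stats::coef(fit)
  dH <- unname(cf[1L])                     # kJ/mol, intercept at 0 degC
  dS_kj <- -unname(cf[2L])                 # kJ/(K mol)
  if (abs(dS_kj) < 1e-12)
    stopf("fitted dS is ~0; the Gibbs line never crosses zero",
          class = "mabtherm_fit_error")
  T_m <- dH / dS_kj
  V <- stats::vcov(fit)
  se_dH <- sqrt(V[1L, 1L])
  se_dS <- sqrt(V[2L, 2L])
  ## delta method for T_m = -b0/b1
  grad <- c(1 / dS_kj, T_m / dS_kj)        # d(Tm)/d(b0), d(Tm)/d(b1) up to sign
  se_Tm <- sqrt(drop(t(grad) %*% V %*% grad))
  list(T_m = T_m,
       dS = dS_kj * 1000,                  # J/(K mol)
       dH_paper = dH,
       dH_vH = dS_kj * celsius_to_kelvin(T_m),
       se = c(T_m = se_Tm, dS = se_dS * 1000, dH_paper = se_dH),
       n = length(keep), fit = fit)
}

## Staircase of van't Hoff steps: f(T) = lev1 + sum_i step_i p_i(T) with
## p_i = 1/(1 + exp(-(dH_i/R)(1/Tm_i(K) - 1/T(K)))) -- the equilibrium
## occupancy of a two-state transition, logistic in 1/T rather than in T.
## Used to pin down the inter-transition reference levels: a Boltzmann
## staircase (symmetric in T) mis-places the plateau levels of sharp
## transitions by a few percent, which ln K amplifies.
fit_vh_staircase <- function(tt, vv, sigmoids) {
  r <- length(sigmoids)
  TK <- celsius_to_kelvin(tt)
  Tmid <- mean(range(tt))
  tc <- tt - Tmid
  T0 <- vapply(sigmoids, `[[`, numeric(1), "T0")
  dT <- vapply(sigmoids, `[[`, numeric(1), "dT")
  ## parameters: base level, r steps, r midpoints, r enthalpies (in units
  ## of 1e5 J/mol so all parameters share a common scale -- LM stalls when
  ## gradients differ by five orders of magnitude), then a linear drift c1.
  ## The drift absorbs the residual baseline tilt that constant-referenced
  ## (peak-referenced) curves retain, making the reference "levels" lines
  ## in T. A level-proportional modulation term was considered and rejected:
  ## it halves the residual bias but nearly doubles the reference variance.
  par <- c(sigmoids[[1L]]$A1,
           vapply(sigmoids, function(s) s$A2 - s$A1, numeric(1)),
           T0,
           .R_GAS * celsius_to_kelvin(T0)^2 / dT / 1e5,  # init from width
           0)
  comp <- function(p) {
    c1 <- p[2L + 3L * r]
    v <- p[1L] + c1 * tc
    for (i in seq_len(r)) {
      TmK <- celsius_to_kelvin(p[1L + r + i])
      v <- v + p[1L + i] /
        (1 + exp(-(abs(p[1L + 2L * r + i]) * 1e5 / .R_GAS) * (1 / TmK - 1 / TK)))
    }
    v
  }
  out <- tryCatch(nlslm_fit(par, function(p) vv - comp(p),
                            context = "van't Hoff staircase"),
                  error = function(e) NULL)
  if (is.null(out)) return(NULL)
  p <- out$par
  Tm <- p[(2L + r):(1L + 2L * r)]
  if (is.unsorted(Tm, strictly = TRUE) || any(Tm < min(tt) | Tm > max(tt)))
    return(NULL)
  base <- p[1L]
  steps <- p[2L:(1L + r)]
  c1 <- p[2L + 3L * r]
  ## boundary reference lines: model value with the first k-1 transitions
  ## complete and the rest not started
  refs <- lapply(0:r, function(k) {
    lk <- if (k == 0L) 0 else sum(steps[seq_len(k)])
    list(intercept = base + lk - c1 * Tmid, slope = c1)
  })
  list(levels = base + cumsum(c(0, steps)), refs = refs, T_m = Tm,
       dH_vH = abs(p[(2L + 2L * r):(1L + 3L * r)]) * 1e5)
}

#' Per-region two-state thermodynamics
#'
#' Runs the full per-region chain: region-local fraction, equilibrium
#' constant K = f/(1-f) (points with f outside (epsilon_f, 1 - epsilon_f)
#' excluded), Gibbs energy Delta G = -RT ln K, and the linear transition-
#' window fit yielding T_m, dS, dH.
#'
#' @inheritParams region_fraction
#' @param index Region index (1-based), for labelling.
#' @param epsilon_f Exclusion margin on f before taking ln K (default 0.02).
#' @param dG_window Transition window half-width, kJ/mol (default 5).
#' @return An object of class \code{"region_thermo"}.
#' @export
region_thermo <- function(curve, sigmoid, low_ref = NULL, high_ref = NULL,
                          index = 1L, epsilon_f = 0.02, dG_window = 5) {
  rf <- region_fraction(curve, sigmoid, low_ref, high_ref)
  keep <- rf$f_i > epsilon_f & rf$f_i < 1 - epsilon_f
  if (sum(keep) < 3L)
    stopf("region %d: fewer than 3 points with f in (%g, %g)", index,
          epsilon_f, 1 - epsilon_f, class = "mabtherm_fit_error")
  tt <- rf$T[keep]; ff <- rf$f_i[keep]
  K <- equilibrium_constant(ff)
  dG <- gibbs(K, tt)
  ## anchor the |dG| < window selection on the fitted sigmoid rather than
  ## on each point's own noisy dG: the expected dG crosses the window at
  ## |T - T0| = window / dS0 with dS0 = R T_m(K) / dT, so membership is
  ## deterministic and not co-selected with the noise
  dS0 <- .R_GAS * celsius_to_kelvin(sigmoid$T0) / sigmoid$dT / 1000  # kJ/(K mol)
  T_halfwidth <- dG_window / dS0
  sel <- abs(tt - sigmoid$T0) <= T_halfwidth
  lt <- if (sum(sel) >= 3L)
    linear_transition_fit(tt[sel], dG[sel], window = Inf)
  else linear_transition_fit(tt, dG, window = dG_window)
  structure(list(index = as.integer(index),
                 T_m = lt$T_m, dS = lt$dS, dH_paper = lt$dH_paper,
                 dH_vH = lt$dH_vH, se = lt$se, n = lt$n,
                 curve = data.frame(T = tt, f_i = ff, K = K, dG = dG),
                 sigmoid = sigmoid),
            class = "region_thermo")
}

#' @export
print.region_thermo <- function(x, ...) {
  cat(sprintf("Region %d: T_m = %.2f degC, dH = %.3g kJ/mol, dS = %.3g J/(K mol) [dH_vH = %.3g kJ/mol]\n",
              x$index, x$T_m, x$dH_paper, x$dS, x$dH_vH))
  invisible(x)
}

#' Total thermodynamics over all transition regions
#'
#' Sums the per-region enthalpies and entropies and evaluates the total
#' Gibbs energy change dG_total = dH_total - T_ref x dS_total/1000 (kJ/mol)
#' with the temperature on the Celsius axis, consistent with the per-region
#' convention. T_ref defaults to the last intersection temperature (the
#' free-energy minimum separating the final two regimes), falling back to
#' the last region's T_m for single-region data; this reference choice is a
#' reporting convention and is recorded on the result. Uncertainties combine
#' in quadrature.
#'
#' @param regions List of \code{"region_thermo"} objects.
#' @param T_ref Reference temperature, degC; default as described.
#' @param T_I Optional intersection temperatures used for the default
#'   \code{T_ref}.
#' @return An object of class \code{"thermo_summary"} with \code{dH_total}
#'   (kJ/mol), \code{dS_total} (J/(K mol)), \code{dG_total} (kJ/mol),
#'   \code{T_ref}, \code{T_ref_rule} and propagated \code{se}.
#' @export
totals <- function(regions, T_ref = NULL, T_I = NULL) {
  if (!length(regions))
    stopf("no regions supplied", class = "mabtherm_validation_error")
  rule <- "user"
  if (is.null(T_ref)) {
    if (length(T_I)) { T_ref <- T_I[length(T_I)]; rule <- "last_intersection" }
    else { T_ref <- regions[[length(regions)]]$T_m; rule <- "last_T_m" }
  }
  dH <- sum(vapply(regions, `[[`, numeric(1), "dH_paper"))
  dS <- sum(vapply(regions, `[[`, numeric(1), "dS"))
  se_dH <- sqrt(sum(vapply(regions, function(r) r$se[["dH_paper"]]^2, numeric(1))))
  se_dS <- sqrt(sum(vapply(regions, function(r) r$se[["dS"]]^2, numeric(1))))
  dG <- dH - T_ref * dS / 1000
  se_dG <- sqrt(se_dH^2 + (T_ref / 1000)^2 * se_dS^2)
  structure(list(dH_total = dH, dS_total = dS, dG_total = dG,
                 T_ref = T_ref, T_ref_rule = rule,
                 se = c(dH_total = se_dH, dS_total = se_dS, dG_total = se_dG),
                 n_regions = length(regions)),
            class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat(sprintf("Totals over %d region(s): dH_total = %.4g kJ/mol, dS_total = %.4g J/(K mol)\n",
              x$n_regions, x$dH_total, x$dS_total))
  cat(sprintf("  dG_total = %.4g kJ/mol at T_ref = %.2f degC (rule: %s; reporting convention)\n",
              x$dG_total, x$T_ref, x$T_ref_rule))
  invisible(x)
}
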