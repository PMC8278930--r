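#' BLI sensorgram container
#'
#' A bio-layer interferometry trace: response (nm) versus time (s) with phase
#' annotations (\code{baseline}, \code{association}, \code{dissociation}) and
#' the molar analyte concentration during association.
#'
#' @param t Time, s; strictly increasing.
#' @param R Response, nm.
#' @param phase Character vector of phase labels, one per point.
#' @param C Molar analyte concentration during association, M (> 0).
#' @return An object of class \code{"sensorgram"}.
#' @export
sensorgram <- function(t, R, phase, C) {
  t <- as.numeric(t); R <- as.numeric(R); phase <- as.character(phase)
  if (length(t) != length(R) || length(t) != length(phase))
    stopf("t, R and phase must have equal length", class = "mabtherm_validation_error")
  if (!is_strictly_increasing(t))
    stopf("t must be strictly increasing", class = "mabtherm_validation_error")
  ok <- phase %in% c("baseline", "association", "dissociation")
  if (!all(ok))
    stopf("unknown phase label '%s'", phase[!ok][1L], class = "mabtherm_validation_error")
  check_number(C, "C", positive = TRUE)
  structure(list(t = t, R = R, phase = phase, C = C), class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram: %d points over %.4g s, C = %.3g M; phases: %s\n",
              length(x$t), diff(range(x$t)), x$C,
              paste(unique(x$phase), collapse = ", ")))
  invisible(x)
}

#' Convert a mass concentration to molar
#'
#' C (mol/L) = c (mg/mL) / MW (g/mol): a mg/mL is a g/L, so dividing by the
#' molar mass gives mol/L directly.
#'
#' @param c_mg_ml Mass concentration, mg/mL (> 0).
#' @param mw Molar mass, g/mol (> 0).
#' @return Molar concentration, M.
#' @examples
#' mass_to_molar(0.96, 146000)  # 6.58e-6 M
#' @export
mass_to_molar <- function(c_mg_ml, mw) {
  check_number(c_mg_ml, "c_mg_ml", positive = TRUE)
  check_number(mw, "mw", positive = TRUE)
  c_mg_ml / mw
}

#' Equilibrium dissociation constant
#'
#' K_D = k_off / k_on, the analyte concentration at which half the ligand
#' sites are occupied at equilibrium; lower K_D means tighter binding.
#'
#' @param kon Association rate constant, 1/(M s) (> 0).
#' @param koff Dissociation rate constant, 1/s.
#' @return K_D in M.
#' @examples
#' compute_KD(1e5, 1e-3)  # 1e-8 M
#' @export
compute_KD <- function(kon, koff) {
  if (any(kon <= 0))
    stopf("kon must be > 0", class = "mabtherm_domain_error")
  koff / kon
}

## closed-form 1:1 response over one association + dissociation cycle.
## times are absolute; t_assoc0/t_dissoc0 are the phase start times.
r_1to1 <- function(t, kon, koff, Rmax, C, t_assoc0, t_dissoc0) {
  kobs <- kon * C + koff
  Req <- Rmax * C / (C + koff / kon)
  R <- numeric(length(t))
  assoc <- t >= t_assoc0 & t < t_dissoc0
  diss <- t >= t_dissoc0
  R[assoc] <- Req * (1 - exp(-kobs * (t[assoc] - t_assoc0)))
  R_end <- Req * (1 - exp(-kobs * (t_dissoc0 - t_assoc0)))
  R[diss] <- R_end * exp(-koff * (t[diss] - t_dissoc0))
  R
}

#' Simulate a 1:1 binding sensorgram
#'
#' Closed-form pseudo-first-order kinetics: during association
#' R(t) = Req (1 - exp(-(kon C + koff) t)) with
#' Req = Rmax C / (C + koff/kon); during dissociation the response decays as
#' exp(-koff (t - t_d)). Baseline response is 0. Analyte depletion is
#' neglected (C constant).
#'
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @param Rmax Maximal response, nm.
#' @param C Analyte concentration, M.
#' @param t_baseline,t_assoc,t_dissoc Phase durations, s.
#' @param dt Sampling interval, s.
#' @return A [sensorgram()].
#' @export
simulate_1to1 <- function(kon, koff, Rmax, C, t_baseline = 60,
                          t_assoc = 120, t_dissoc = 120, dt = 0.2) {
  if (any(c(t_baseline, t_assoc, t_dissoc) < 0) || t_assoc <= 0 || t_dissoc <= 0)
    stopf("phase durations must be > 0", class = "mabtherm_validation_error")
  t <- seq(0, t_baseline + t_assoc + t_dissoc, by = dt)
  ta <- t_baseline; td <- t_baseline + t_assoc
  R <- if (C > 0) r_1to1(t, kon, koff, Rmax, C, ta, td) else numeric(length(t))
  phase <- ifelse(t < ta, "baseline", ifelse(t < td, "association", "dissociation"))
  sg <- sensorgram(t, R, phase, C = max(C, .Machine$double.xmin))
  sg$C <- C
  sg
}

#' Simulate a 1:2 (bivalent analyte) sensorgram
#'
#' Two model forms for the biphasic binding of a bivalent analyte (an
#' antibody bridging two sensor ligands):
#' \describe{
#'   \item{\code{parallel_sites} (default)}{R(t) = R1(t) + R2(t), each phase
#'     following the 1:1 closed forms with its own (kon, koff, Rmax) set --
#'     the parameterisation used when fitting independent first/second
#'     binding phases.}
#'   \item{\code{sequential_bivalent}}{mechanistic avidity scheme
#'     A + L <-> AL, AL + L <-> AL2 integrated as ODEs on site fractions
#'     (free sites L = 1 - [AL] - 2[AL2], all per total sites). \code{kon2}
#'     here is an effective rate (1/s) multiplying the free-site fraction,
#'     since the molarity of immobilised sites is not defined for a BLI tip.
#'     Response is Rmax1 ([AL] + [AL2]) -- full occupancy maps to Rmax1;
#'     \code{Rmax2} is ignored in this form.}
#' }
#'
#' @param kon1,koff1,Rmax1 First-phase constants (as in [simulate_1to1()]).
#' @param kon2,koff2,Rmax2 Second-phase constants.
#' @param C Analyte concentration, M.
#' @param model_form \code{"parallel_sites"} or \code{"sequential_bivalent"}.
#' @param t_baseline,t_assoc,t_dissoc Phase durations, s.
#' @param dt Sampling interval, s.
#' @return A [sensorgram()]. For \code{sequential_bivalent} the species
#'   trajectories are attached as \code{attr(, "species")}.
#' @export
simulate_1to2 <- function(kon1, koff1, Rmax1, kon2, koff2, Rmax2, C,
                          model_form = c("parallel_sites", "sequential_bivalent"),
                          t_baseline = 60, t_assoc = 120, t_dissoc = 120,
                          dt = 0.2) {
  model_form <- match.arg(model_form)
  if (model_form == "parallel_sites") {
    s1 <- simulate_1to1(kon1, koff1, Rmax1, C, t_baseline, t_assoc, t_dissoc, dt)
    R2 <- if (kon2 > 0 && Rmax2 > 0)
      r_1to1(s1$t, kon2, koff2, Rmax2, C, t_baseline, t_baseline + t_assoc)
    else numeric(length(s1$t))
    s1$R <- s1$R + R2
    return(s1)
  }
  ## sequential bivalent: site-fraction ODEs
  t <- seq(0, t_baseline + t_assoc + t_dissoc, by = dt)
  ta <- t_baseline; td <- t_baseline + t_assoc
  deriv <- function(time, y, parms) {
    al <- y[1L]; al2 <- y[2L]
    l <- 1 - al - 2 * al2
    Ct <- if (time >= ta && time < td) C else 0
    d_al <- parms$kon1 * Ct * l - parms$koff1 * al -
      parms$kon2 * al * l + parms$koff2 * al2
    d_al2 <- parms$kon2 * al * l - parms$koff2 * al2
    list(c(d_al, d_al2))
  }
  sol <- deSolve::ode(y = c(al = 0, al2 = 0), times = t, func = deriv,
                      parms = list(kon1 = kon1, koff1 = koff1,
                                   kon2 = kon2, koff2 = koff2),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0)
    stopf("ODE integration failed (istate %d)", attr(sol, "istate")[1L],
          class = "mabtherm_solver_error")
  al <- sol[, "al"]; al2 <- sol[, "al2"]
  R <- Rmax1 * (al + al2)
  phase <- ifelse(t < ta, "baseline", ifelse(t < td, "association", "dissociation"))
  sg <- sensorgram(t, R, phase, C = C)
  attr(sg, "species") <- data.frame(t = t, AL = al, AL2 = al2,
                                    L = 1 - al - 2 * al2)
  sg
}

## residuals of the closed-form parallel model against a sensorgram
bli_model_response <- function(par, sg, n_comp) {
  ta <- min(sg$t[sg$phase == "association"])
  td <- min(sg$t[sg$phase == "dissociation"])
  R <- numeric(length(sg$t))
  for (j in seq_len(n_comp)) {
    kon <- exp(par[3 * j - 2]); koff <- exp(par[3 * j - 1]); Rmax <- exp(par[3 * j])
    R <- R + r_1to1(sg$t, kon, koff, Rmax, sg$C, ta, td)
  }
  R
}

## linearised initial estimates: koff from the log-linear dissociation tail,
## kon from the observed association rate kobs = kon C + koff
bli_init <- function(sg) {
  diss <- which(sg$phase == "dissociation")
  assoc <- which(sg$phase == "association")
  if (!length(diss))
    stopf("no dissociation phase: cannot estimate koff", class = "mabtherm_fit_error")
  if (!length(assoc))
    stopf("no association phase", class = "mabtherm_fit_error")
  R0 <- sg$R[diss[1L]]
  if (max(abs(sg$R)) <= 0)
    stopf("flat zero trace: no signal to fit", class = "mabtherm_fit_error")
  ## log-linear early dissociation tail (first ~40% where R stays positive)
  td <- sg$t[diss[1L]]
  keep <- diss[sg$R[diss] > 0.05 * max(R0, .Machine$double.eps)]
  if (length(keep) < 3L) keep <- diss[seq_len(min(5L, length(diss)))]
  lf <- stats::lm(log(pmax(sg$R[keep], 1e-12)) ~ I(sg$t[keep] - td))
  koff0 <- max(-unname(stats::coef(lf)[2L]), 1e-6)
  ## observed rate from the association rise
  ta <- sg$t[assoc[1L]]
  Rinf <- max(sg$R[assoc])
  frac <- 1 - sg$R[assoc] / (Rinf * 1.05)
  ok <- assoc[frac > 0.05 & frac < 0.95]
  kobs0 <- if (length(ok) >= 3L) {
    af <- stats::lm(log(frac[match(ok, assoc)]) ~ I(sg$t[ok] - ta))
    max(-unname(stats::coef(af)[2L]), 1e-4)
  } else 0.05
  kon0 <- max((kobs0 - koff0) / sg$C, 1e2)
  list(kon = kon0, koff = koff0, Rmax = max(Rinf, 1e-3))
}

#' Fit a sensorgram with a 1:1 or 1:2 binding model
#'
#' Nonlinear least squares over log-scaled rate parameters (Levenberg-
#' Marquardt), using the closed-form 1:1 response per component; the 1:2
#' model is the two-component (parallel-sites) parameterisation with
#' independent (kon, koff, Rmax) per binding phase. Initialisation is
#' deterministic, from linearised estimates: koff from the log-linear
#' dissociation tail, kon from the observed rate kobs = kon C + koff. RMSE is
#' reported per model so a 1:1 vs 1:2 comparison can mirror experimental
#' model rejection. Fits whose parameters run to the working range limits are
#' reported with \code{converged = FALSE}.
#'
#' @param sg A [sensorgram()] with association and dissociation phases.
#' @param model \code{"one_to_one"} or \code{"one_to_two"}.
#' @return An object of class \code{"bli_fit"}: \code{params} (named list),
#'   \code{KD} (M, koff1/kon1), \code{rss}, \code{rmse}, \code{se},
#'   \code{converged}, \code{model}.
#' @export
bli_fit <- function(sg, model = c("one_to_two", "one_to_one")) {
  stopifnot(inherits(sg, "sensorgram"))
  model <- match.arg(model)
  n_comp <- if (model == "one_to_one") 1L else 2L
  ini <- bli_init(sg)
  resid_fn <- function(p) sg$R - bli_model_response(p, sg, n_comp)
  starts <- if (n_comp == 1L) {
    list(log(c(ini$kon, ini$koff, ini$Rmax)))
  } else {
    ## deterministic multi-start: split the 1:1 estimates into a fast and a
    ## slow component at several ratios (biphasic traces are prone to local
    ## minima from a single start)
    out <- list()
    for (s in c(3, 10, 30))
      for (pat in list(c(1, -1), c(1, 1)))   # slow phase: slower or faster koff
        out[[length(out) + 1L]] <-
          log(c(ini$kon * s, ini$koff * s^pat[2L], ini$Rmax * 0.6,
                ini$kon / s, ini$koff / s^pat[2L], ini$Rmax * 0.4))
    out
  }
  best <- NULL
  for (p0 in starts) {
    cand <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-12, ptol = 1e-12))
    if (is.null(best) || sum(cand$fvec^2) < sum(best$fvec^2)) best <- cand
  }
  fit <- best
  p <- fit$par
  n <- length(sg$t)
  rss <- sum(fit$fvec^2)
  est <- exp(p)
  nm <- if (n_comp == 1L) c("kon", "koff", "Rmax")
        else c("kon1", "koff1", "Rmax1", "kon2", "koff2", "Rmax2")
  names(est) <- nm
  if (n_comp == 2L && est[["kon1"]] < est[["kon2"]]) {
    ## order components so phase 1 is the faster association
    est <- est[c(4:6, 1:3)]
    names(est) <- nm
    p <- log(unname(est))
  }
  within_range <- all(est > 1e-12 & est < 1e12)
  converged <- fit$info %in% 1:4 && within_range
  se <- tryCatch({
    J <- fit$hessian
    cv <- solve(J) * rss / (n - length(p))
    sqrt(pmax(diag(cv), 0)) * est      # delta method back from log scale
  }, error = function(e) rep(NA_real_, length(p)))
  names(se) <- nm
  kon1 <- est[[1L]]; koff1 <- est[[2L]]
  structure(list(model = model, params = as.list(est),
                 KD = compute_KD(kon1, koff1),
                 rss = rss, rmse = sqrt(rss / n), n = n,
                 se = se, converged = converged, C = sg$C,
                 sensorgram = sg),
            class = "bli_fit")
}

#' @export
print.bli_fit <- function(x, ...) {
  cat(sprintf("BLI %s fit (%sconverged): KD = %.3g M, rmse = %.3g nm\n",
              if (x$model == "one_to_one") "1:1" else "1:2",
              if (x$converged) "" else "NOT ", x$KD, x$rmse))
  p <- unlist(x$params)
  cat(" ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.bli_fit <- function(object, ...) unlist(object$params)

#' @export
predict.bli_fit <- function(object, newdata = NULL, ...) {
  sg <- if (is.null(newdata)) object$sensorgram else newdata
  n_comp <- if (object$model == "one_to_one") 1L else 2L
  bli_model_response(log(unlist(object$params)), sg, n_comp)
}

#' @export
fitted.bli_fit <- function(object, ...) predict(object)

#' @export
residuals.bli_fit <- function(object, ...)
  object$sensorgram$R - predict(object)

#' Plot a BLI fit
#' @param x A \code{"bli_fit"}.
#' @param ... Passed to \code{plot()}.
#' @export
plot.bli_fit <- function(x, ...) {
  sg <- x$sensorgram
  graphics::plot(sg$t, sg$R, xlab = "Time (s)", ylab = "Response (nm)",
                 col = "grey50", pch = 16, cex = 0.4, ...)
  graphics::lines(sg$t, predict(x), col = 2, lwd = 2)
  graphics::abline(v = c(min(sg$t[sg$phase == "association"]),
                         min(sg$t[sg$phase == "dissociation"])),
                   lty = 3, col = "grey70")
  invisible(x)
}
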