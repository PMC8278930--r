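## extract (temperature, value) pairs from a curve or signal
get_tv <- function(x) {
  if (inherits(x, "beta_fraction")) list(t = x$temperatures, v = x$f)
  else if (inherits(x, "melt_signal")) list(t = x$temperatures, v = x$y)
  else if (is.list(x) && !is.null(x$temperatures) && !is.null(x$f))
    list(t = x$temperatures, v = x$f)
  else stopf("expected a beta_fraction curve or melt_signal")
}

## centred running mean, ends padded by the first/last full value
running_mean <- function(x, k = 5L) {
  n <- length(x)
  if (n < k) return(x)
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  half <- (k - 1L) %/% 2L
  sm[seq_len(half)] <- sm[half + 1L]
  sm[(n - half + 1L):n] <- sm[n - half]
  sm
}

## OLS on a window; returns slope, intercept, r2, rmse
window_fit <- function(tt, vv) {
  n <- length(tt)
  mx <- mean(tt); my <- mean(vv)
  sxx <- sum((tt - mx)^2)
  b <- sum((tt - mx) * (vv - my)) / sxx
  a <- my - b * mx
  res <- vv - (a + b * tt)
  rss <- sum(res^2)
  tss <- sum((vv - my)^2)
  list(slope = b, intercept = a,
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       rmse = sqrt(rss / n), n = n)
}

## Levenberg-Marquardt least squares on a residual function, with
## convergence check and covariance-based standard errors.
## Deliberately unbounded: nls.lm's bounded mode loses its automatic
## parameter scaling and stalls on badly scaled problems; callers enforce
## constraints by reparameterisation/canonicalisation instead.
nlslm_fit <- function(par, fn, context = "fit") {
  fit <- minpack.lm::nls.lm(
    par = par, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!(fit$info %in% 1:4))
    stopf("%s did not converge: %s", context, fit$message,
          class = "mabtherm_fit_error")
  rss <- sum(fit$fvec^2)
  n <- length(fit$fvec)
  se <- tryCatch({
    dfree <- max(n - length(par), 1L)
    sqrt(pmax(diag(solve(fit$hessian)), 0) * rss / dfree)
  }, error = function(e) rep(NA_real_, length(par)))
  names(se) <- names(par)
  list(par = fit$par, rss = rss, n = n, se = se)
}

plateau_obj <- function(tt, idx, fit) {
  structure(list(T_range = c(tt[idx[1L]], tt[idx[2L]]),
                 slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, rmse = fit$rmse,
                 n_points = idx[2L] - idx[1L] + 1L,
                 idx = idx), class = "plateau")
}

#' @export
print.plateau <- function(x, ...) {
  cat(sprintf("Plateau %.4g-%.4g degC: %d points, slope %.4g /degC, r2 %.4g\n",
              x$T_range[1], x$T_range[2], x$n_points, x$slope, x$r_squared))
  invisible(x)
}

#' Detect linear plateau regions of a melt curve
#'
#' Identifies the ordered, disjoint near-linear plateau regions separating
#' sigmoidal transitions. Windows of \code{min_points} are seeded at both
#' data ends and at local minima of a coarse smoothed derivative, then grown
#' greedily point-by-point while the window's least-squares line keeps
#' \code{|slope| <= slope_tol} and a fit RMSE no larger than a noise-scaled
#' cap; overlapping windows are merged when their union still qualifies.
#' Deterministic: no random restarts.
#'
#' @param curve A [beta_fraction_curve()] (or [melt_signal()]; the raw values
#'   are then used, with \code{slope_tol} interpreted in signal units/degC).
#' @param min_points Minimum plateau size, points (default 5).
#' @param slope_tol Maximum admissible plateau |slope| in curve units per
#'   degree C (default 0.02 for a [0, 1]-scaled fraction curve).
#' @param r2_floor r-squared used for the single-line fallback when no flat
#'   plateau exists (a globally linear data set is returned as one plateau).
#' @return A list of \code{"plateau"} objects, ordered by temperature.
#' @export
detect_plateaus <- function(curve, min_points = 5L, slope_tol = 0.02,
                            r2_floor = 0.98) {
  tv <- get_tv(curve)
  tt <- tv$t; vv <- tv$v
  n <- length(tt)
  min_points <- max(3L, as.integer(min_points))
  if (n < 2L * min_points)
    stopf("need at least %d points for plateau detection (have %d)",
          2L * min_points, n, class = "mabtherm_segmentation_error")

  ## robust noise scale from the lower quartile of successive differences:
  ## the median is inflated by transition structure, the quartile tracks the
  ## flattest stretches (half-normal: sigma = q25 / 0.4506)
  sigma_hat <- 2.219 * unname(stats::quantile(abs(diff(vv)), 0.25))
  ## structural floor: quasi-plateaus between transitions are gently curved
  ## even without noise; growth across transitions is prevented by the
  ## derivative block below, not by this cap
  rmse_cap <- max(2 * sigma_hat, 5e-3 * diff(range(vv)), .Machine$double.eps)
  admissible <- function(fit) abs(fit$slope) <= slope_tol && fit$rmse <= rmse_cap

  ## seeds: both ends plus local minima of the coarse |derivative|
  sm <- running_mean(vv, 5L)
  d <- c(NA_real_, (sm[-(1:2)] - sm[1:(n - 2)]) / (tt[-(1:2)] - tt[1:(n - 2)]), NA_real_)
  ad <- abs(d)
  interior <- which(!is.na(ad))
  locmin <- interior[vapply(interior, function(i) {
    lo <- max(2L, i - 2L); hi <- min(n - 1L, i + 2L)
    ad[i] <= min(ad[lo:hi], na.rm = TRUE)
  }, logical(1))]
  half <- (min_points - 1L) %/% 2L
  starts <- unique(pmax(1L, pmin(n - min_points + 1L,
                                 c(1L, n - min_points + 1L, locmin - half))))
  starts <- sort(starts)

  ## points on a steep flank (strong coarse derivative) cannot join a
  ## plateau: prevents windows creeping across a transition
  blocked <- !is.na(ad) & ad > 1.5 * slope_tol

  windows <- list()
  for (s in starts) {
    lo <- s; hi <- s + min_points - 1L
    fit <- window_fit(tt[lo:hi], vv[lo:hi])
    if (!admissible(fit)) next
    repeat {
      cand <- list()
      if (lo > 1L && !blocked[lo - 1L]) {
        fl <- window_fit(tt[(lo - 1L):hi], vv[(lo - 1L):hi])
        if (admissible(fl)) cand$left <- fl
      }
      if (hi < n && !blocked[hi + 1L]) {
        fr <- window_fit(tt[lo:(hi + 1L)], vv[lo:(hi + 1L)])
        if (admissible(fr)) cand$right <- fr
      }
      if (!length(cand)) break
      pick <- if (length(cand) == 2L) {
        if (cand$left$rmse <= cand$right$rmse) "left" else "right"
      } else names(cand)[1L]
      if (pick == "left") { lo <- lo - 1L; fit <- cand$left }
      else { hi <- hi + 1L; fit <- cand$right }
    }
    windows[[length(windows) + 1L]] <- list(idx = c(lo, hi), fit = fit)
  }

  if (!length(windows)) {
    ## fallback: globally linear data counts as a single plateau
    gfit <- window_fit(tt, vv)
    if (gfit$r_squared >= r2_floor) {
      p <- plateau_obj(tt, c(1L, n), gfit)
      attr(p, "global_line") <- TRUE
      return(list(p))
    }
    stopf("no admissible plateau found; consider supplying manual baseline ranges",
          class = "mabtherm_segmentation_error")
  }

  ## sort, drop duplicates/contained windows, merge or trim overlaps
  windows <- windows[order(vapply(windows, function(w) w$idx[1L], integer(1)),
                           vapply(windows, function(w) -w$idx[2L], integer(1)))]
  merged <- list(windows[[1L]])
  for (w in windows[-1L]) {
    last <- merged[[length(merged)]]
    if (w$idx[2L] <= last$idx[2L]) next                     # contained
    if (w$idx[1L] <= last$idx[2L]) {                        # overlap
      u <- c(last$idx[1L], w$idx[2L])
      uf <- window_fit(tt[u[1L]:u[2L]], vv[u[1L]:u[2L]])
      if (admissible(uf)) {
        merged[[length(merged)]] <- list(idx = u, fit = uf)
      } else {
        lo <- last$idx[2L] + 1L                             # trim the newcomer
        if (w$idx[2L] - lo + 1L >= min_points) {
          tf <- window_fit(tt[lo:w$idx[2L]], vv[lo:w$idx[2L]])
          if (admissible(tf))
            merged[[length(merged) + 1L]] <- list(idx = c(lo, w$idx[2L]), fit = tf)
        }
      }
    } else merged[[length(merged) + 1L]] <- w
  }
  lapply(merged, function(w) plateau_obj(tt, w$idx, w$fit))
}

#' Fit a Boltzmann sigmoid
#'
#' Least-squares fit of f(T) = A2 + (A1 - A2)/(1 + exp((T - T0)/dT)), the
#' 4-parameter logistic melt model (A1 the initial, A2 the final asymptote,
#' T0 the midpoint, dT > 0 the width). Deterministic initialisation: A1/A2
#' from span endpoints, T0 from the maximum absolute smoothed derivative, dT
#' from a tenth of the span.
#'
#' @param T,y Numeric vectors (temperature, value).
#' @return An object of class \code{"boltzmann_fit"} with fields \code{A1},
#'   \code{A2}, \code{T0}, \code{dT}, \code{rmse}, \code{rss},
#'   \code{fit_T_range}, \code{n}, \code{se} (named standard errors).
#' @export
fit_boltzmann <- function(T, y) {
  n <- length(T)
  if (n < 4L)
    stopf("Boltzmann fit needs >= 4 points (have %d)", n,
          class = "mabtherm_fit_error")
  sm <- running_mean(y, min(5L, n))
  dd <- diff(sm) / diff(T)
  T0_init <- T[which.max(abs(dd))]
  span <- diff(range(T))
  start <- c(A1 = y[1L], A2 = y[n], T0 = T0_init, dT = max(span / 10, 1e-3))
  res_fn <- function(p) y - boltzmann_eval(T, p[1L], p[2L], p[3L], p[4L])
  out <- tryCatch(
    nlslm_fit(start, res_fn, context = "Boltzmann fit"),
    error = function(e)
      stopf("Boltzmann fit failed on span [%g, %g] degC: %s",
            min(T), max(T), conditionMessage(e), class = "mabtherm_fit_error"))
  p <- out$par
  if (p[["dT"]] < 0) {
    ## (A1, A2, dT) -> (A2, A1, -dT) leaves the model invariant; report the
    ## canonical dT > 0 form with A1 the low-temperature asymptote
    p[c("A1", "A2")] <- p[c("A2", "A1")]
    p[["dT"]] <- -p[["dT"]]
    out$se[c("A1", "A2")] <- out$se[c("A2", "A1")]
  }
  rss <- out$rss
  se <- out$se
  if (p[["T0"]] < min(T) || p[["T0"]] > max(T))
    warnf("fitted midpoint T0 = %.2f degC lies outside the fit range [%g, %g]",
          p[["T0"]], min(T), max(T))
  structure(list(A1 = p[["A1"]], A2 = p[["A2"]], T0 = p[["T0"]],
                 dT = p[["dT"]], rss = rss, rmse = sqrt(rss / n),
                 fit_T_range = range(T), n = n, se = se),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann sigmoid: T0 = %.2f degC, dT = %.3g degC, A1 = %.4g, A2 = %.4g (rmse %.3g, n = %d)\n",
              x$T0, x$dT, x$A1, x$A2, x$rmse, x$n))
  invisible(x)
}

#' Predict from a Boltzmann sigmoid fit
#' @param object A \code{"boltzmann_fit"}.
#' @param newdata Temperatures (numeric vector), or a data frame with column
#'   \code{T}.
#' @param ... Unused.
#' @export
predict.boltzmann_fit <- function(object, newdata, ...) {
  T <- if (is.data.frame(newdata)) newdata$T else as.numeric(newdata)
  boltzmann_eval(T, object$A1, object$A2, object$T0, object$dT)
}

## ---- shape models (parabolic / Gaussian / bi-Gaussian guide curves) ----

shape_eval <- function(shape, T) {
  p <- shape$params
  switch(shape$kind,
    parabolic = p$c0 + p$c1 * T + p$c2 * T^2,
    gaussian = p$y_off + p$H * exp(-(T - p$Tc)^2 / (2 * p$sigma^2)),
    bigaussian = {
      s <- ifelse(T <= p$Tc, p$sigma1, p$sigma2)
      p$y_off + p$H * exp(-(T - p$Tc)^2 / (2 * s^2))
    },
    stopf("unknown shape kind '%s'", shape$kind))
}

## deterministic peak-based initialisation shared by the Gaussian forms
gauss_init <- function(tt, vv) {
  med <- stats::median(vv)
  up <- max(vv) - med; down <- med - min(vv)
  if (up >= down) list(H = max(vv) - min(vv), Tc = tt[which.max(vv)], y_off = min(vv))
  else list(H = min(vv) - max(vv), Tc = tt[which.min(vv)], y_off = max(vv))
}

fit_gaussian <- function(tt, vv) {
  ini <- gauss_init(tt, vv)
  start <- c(H = ini$H, Tc = ini$Tc, y_off = ini$y_off,
             sigma = diff(range(tt)) / 6)
  res_fn <- function(p)
    vv - (p[3L] + p[1L] * exp(-(tt - p[2L])^2 / (2 * p[4L]^2)))
  out <- nlslm_fit(start, res_fn, context = "Gaussian shape fit")
  out$par[["sigma"]] <- abs(out$par[["sigma"]])   # enters squared
  p <- as.list(out$par)
  structure(list(kind = "gaussian", params = p, rss = out$rss,
                 rmse = sqrt(out$rss / length(vv)), n_par = 4L),
            class = "shape_model")
}

fit_bigaussian <- function(tt, vv) {
  ini <- gauss_init(tt, vv)
  s0 <- diff(range(tt)) / 6
  start <- c(H = ini$H, Tc = ini$Tc, y_off = ini$y_off,
             sigma1 = s0, sigma2 = s0)
  res_fn <- function(p) {
    s <- ifelse(tt <= p[2L], p[4L], p[5L])
    vv - (p[3L] + p[1L] * exp(-(tt - p[2L])^2 / (2 * s^2)))
  }
  out <- nlslm_fit(start, res_fn, context = "bi-Gaussian shape fit")
  out$par[c("sigma1", "sigma2")] <- abs(out$par[c("sigma1", "sigma2")])
  p <- as.list(out$par)
  structure(list(kind = "bigaussian", params = p, rss = out$rss,
                 rmse = sqrt(out$rss / length(vv)), n_par = 5L),
            class = "shape_model")
}

fit_parabolic <- function(tt, vv) {
  fit <- stats::lm(vv ~ tt + I(tt^2))
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  structure(list(kind = "parabolic",
                 params = list(c0 = unname(cf[1]), c1 = unname(cf[2]),
                               c2 = unname(cf[3])),
                 rss = rss, rmse = sqrt(rss / length(vv)), n_par = 3L),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("Shape model: %s, rmse %.4g\n", x$kind, x$rmse))
  if (!is.null(attr(x, "candidate_rmse"))) {
    cr <- attr(x, "candidate_rmse")
    cat("  candidates:", paste(sprintf("%s = %.4g", names(cr), cr), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit and select the overall shape model of a melt curve
#'
#' Trials parabolic, Gaussian and bi-Gaussian (asymmetric Gaussian: distinct
#' left/right widths about the centre) candidates, computes
#' RMSE = sqrt(RSS/n) for each, and returns the minimum-RMSE model; when two
#' candidates tie within 1e-9 the one with fewer parameters wins. All
#' candidate RMSEs are attached as \code{attr(, "candidate_rmse")}.
#'
#' @param curve A [beta_fraction_curve()] (or anything [get_tv()] accepts).
#' @return A \code{"shape_model"} object.
#' @export
fit_shape_models <- function(curve) {
  tv <- get_tv(curve)
  if (length(tv$t) < 6L)
    stopf("shape-model fitting needs >= 6 points", class = "mabtherm_fit_error")
  cands <- list()
  for (f in list(fit_parabolic, fit_gaussian, fit_bigaussian)) {
    m <- tryCatch(f(tv$t, tv$v), error = function(e) {
      warnf("shape candidate failed: %s", conditionMessage(e)); NULL
    })
    if (!is.null(m)) cands[[m$kind]] <- m
  }
  if (!length(cands))
    stopf("all shape-model candidates failed", class = "mabtherm_fit_error")
  rmses <- vapply(cands, `[[`, numeric(1), "rmse")
  npar <- vapply(cands, `[[`, integer(1), "n_par")
  best_rmse <- min(rmses)
  tied <- which(rmses <= best_rmse + 1e-9)
  pick <- tied[which.min(npar[tied])]
  out <- cands[[pick]]
  attr(out, "candidate_rmse") <- rmses
  out
}

#' Fit the sigmoid chain between plateau regions
#'
#' Fits one Boltzmann sigmoid over each span between sequential plateaus
#' (plateau points included at both ends). When the curve's overall shape is
#' (bi-)Gaussian and the data continue past the last plateau, a final sigmoid
#' is fitted from the last plateau to the end point of the data (the minimum
#' of the fitted shape model). Sigmoids are returned ordered by midpoint T0.
#'
#' For multi-transition curves a joint refinement follows: the whole curve is
#' re-fitted as a single staircase of logistic steps (shared plateau levels,
#' one T0 and width per step) initialised from the span fits. This removes
#' the bias the per-span fits pick up from neighbouring transition tails.
#' The refined parameters replace the span estimates; the original
#' independent span fits are kept in \code{attr(, "span_fits")} (adjacent
#' refined sigmoids share exact asymptote levels and therefore never cross,
#' so intersection temperatures are computed from the span fits).
#'
#' @param curve A [beta_fraction_curve()].
#' @param plateaus Result of [detect_plateaus()].
#' @param shape Optional \code{"shape_model"} from [fit_shape_models()]; used
#'   to define the final span's end point.
#' @param refine Logical: run the joint staircase refinement when more than
#'   one sigmoid is present.
#' @return A list of \code{"boltzmann_fit"} objects ordered by \code{T0}.
#' @export
fit_sigmoid_chain <- function(curve, plateaus, shape = NULL, refine = TRUE) {
  tv <- get_tv(curve)
  tt <- tv$t; vv <- tv$v
  n <- length(tt)
  m <- length(plateaus)
  if (m < 1L)
    stopf("need at least one plateau", class = "mabtherm_segmentation_error")

  spans <- list()
  if (m >= 2L)
    for (i in seq_len(m - 1L))
      spans[[length(spans) + 1L]] <- c(plateaus[[i]]$idx[1L],
                                       plateaus[[i + 1L]]$idx[2L])
  ## final sigmoid: from the m-th plateau to the data end point, which is the
  ## minimum of the fitted (bi-)Gaussian when the curve has that shape
  last_end <- plateaus[[m]]$idx[2L]
  if (last_end < n) {
    idx_end <- n
    if (!is.null(shape) && shape$kind %in% c("gaussian", "bigaussian")) {
      tail_idx <- last_end:n
      idx_end <- tail_idx[which.min(shape_eval(shape, tt[tail_idx]))]
    }
    if (idx_end - last_end >= 4L)
      spans[[length(spans) + 1L]] <- c(plateaus[[m]]$idx[1L], idx_end)
  }
  if (!length(spans))
    stopf("no transition span to fit: plateaus cover the whole curve",
          class = "mabtherm_segmentation_error")

  sigmoids <- list()
  for (sp in spans) {
    idx <- sp[1L]:sp[2L]
    if (length(idx) < 4L) {
      warnf("span [%g, %g] degC has < 4 points; skipped", tt[sp[1L]], tt[sp[2L]])
      next
    }
    sigmoids[[length(sigmoids) + 1L]] <- fit_boltzmann(tt[idx], vv[idx])
  }
  if (!length(sigmoids))
    stopf("no sigmoid could be fitted", class = "mabtherm_fit_error")
  sigmoids <- sigmoids[order(vapply(sigmoids, `[[`, numeric(1), "T0"))]
  if (refine && length(sigmoids) > 1L)
    sigmoids <- refine_chain(sigmoids, tt, vv)
  sigmoids
}

## joint staircase refit: f(T) = level0 + sum_i step_i logistic((T-T0_i)/dT_i)
refine_chain <- function(sigmoids, tt, vv) {
  r <- length(sigmoids)
  par <- c(sigmoids[[1L]]$A1,
           vapply(sigmoids, function(s) s$A2 - s$A1, numeric(1)),
           vapply(sigmoids, `[[`, numeric(1), "T0"),
           vapply(sigmoids, `[[`, numeric(1), "dT"))
  comp <- function(p, T) {
    v <- rep(p[1L], length(T))
    for (i in seq_len(r))
      v <- v + p[1L + i] / (1 + exp(-(T - p[1L + r + i]) / abs(p[1L + 2L * r + i])))
    v
  }
  out <- tryCatch(nlslm_fit(par, function(p) vv - comp(p, tt),
                            context = "sigmoid chain refinement"),
                  error = function(e) NULL)
  if (is.null(out)) return(sigmoids)
  p <- out$par
  T0n <- p[(2L + r):(1L + 2L * r)]
  dTn <- abs(p[(2L + 2L * r):(1L + 3L * r)])
  ## accept only a sane refinement: ordering kept, midpoints inside the data
  if (is.unsorted(T0n, strictly = TRUE) ||
      any(T0n < min(tt) | T0n > max(tt)) || any(dTn > diff(range(tt))))
    return(sigmoids)
  lev <- cumsum(c(p[1L], p[2L:(1L + r)]))
  fitted_all <- comp(p, tt)
  refined <- sigmoids
  for (i in seq_len(r)) {
    s <- sigmoids[[i]]
    idx <- tt >= s$fit_T_range[1L] & tt <= s$fit_T_range[2L]
    rss_i <- sum((vv[idx] - fitted_all[idx])^2)
    refined[[i]] <- structure(
      list(A1 = lev[i], A2 = lev[i + 1L], T0 = T0n[i], dT = dTn[i],
           rss = rss_i, rmse = sqrt(rss_i / sum(idx)),
           fit_T_range = s$fit_T_range, n = sum(idx),
           se = c(A1 = NA_real_, A2 = NA_real_,
                  T0 = unname(out$se[1L + r + i]),
                  dT = unname(out$se[1L + 2L * r + i]))),
      class = "boltzmann_fit")
  }
  attr(refined, "span_fits") <- sigmoids
  refined
}

#' Intersection temperature of two adjacent sigmoids
#'
#' The temperature at which the two fitted sigmoids predict the same
#' beta-sheet content, located by bracketed root-finding on
#' \code{[s1$T0, s2$T0]}; if the difference does not change sign there the
#' bracket is widened once to the joint fit range.
#'
#' @param s1,s2 \code{"boltzmann_fit"} objects with \code{s1$T0 < s2$T0}.
#' @return Intersection temperature, degrees C.
#' @export
intersection_temperature <- function(s1, s2) {
  if (!(s1$T0 < s2$T0))
    stopf("require s1$T0 < s2$T0", class = "mabtherm_validation_error")
  g <- function(T) boltzmann_eval(T, s1$A1, s1$A2, s1$T0, s1$dT) -
                   boltzmann_eval(T, s2$A1, s2$A2, s2$T0, s2$dT)
  ## scan for sign changes (endpoint values alone can miss paired crossings
  ## when the fitted asymptote levels do not match exactly); among multiple
  ## crossings take the one nearest the midpoint between the two T0
  find_bracket <- function(lo, hi) {
    grid <- seq(lo, hi, length.out = 2001L)
    gv <- g(grid)
    sc <- which(gv[-1L] * gv[-length(gv)] <= 0 & is.finite(gv[-1L]))
    if (!length(sc)) return(NULL)
    mid <- (s1$T0 + s2$T0) / 2
    centres <- (grid[sc] + grid[sc + 1L]) / 2
    i <- sc[which.min(abs(centres - mid))]
    c(grid[i], grid[i + 1L])
  }
  br <- find_bracket(s1$T0, s2$T0)
  if (is.null(br))
    br <- find_bracket(min(s1$fit_T_range[1L], s2$fit_T_range[1L]),
                       max(s1$fit_T_range[2L], s2$fit_T_range[2L]))
  if (is.null(br))
    stopf("sigmoids do not cross within the joint fit range",
          class = "mabtherm_intersection_error")
  if (g(br[1L]) == 0) return(br[1L])
  stats::uniroot(g, br, tol = 1e-10)$root
}

#' Onset temperature of the first conformational transition
#'
#' Default (\code{"tangent"}): the thermal-analysis onset construction, the
#' intersection of the low-temperature plateau line with the tangent to the
#' first sigmoid at its midpoint (tangent slope (A2 - A1)/(4 dT)). For a flat
#' plateau at the initial asymptote this reduces to T0 - 2 dT.
#' Alternative (\code{"threshold"}): the temperature at which the curve first
#' covers a configured fraction of the first sigmoid's amplitude, linearly
#' interpolated between grid points. Either way this is a reporting
#' convention, not a physical constant; reports label it as such.
#'
#' @param curve A [beta_fraction_curve()] (used in threshold mode).
#' @param first_sigmoid The first \code{"boltzmann_fit"} of the chain.
#' @param low_plateau The low-temperature \code{"plateau"}.
#' @param mode \code{"tangent"} (default) or \code{"threshold"}.
#' @param threshold Amplitude fraction for threshold mode (default 0.05).
#' @return Onset temperature, degrees C.
#' @export
onset_temperature <- function(curve, first_sigmoid, low_plateau,
                              mode = c("tangent", "threshold"),
                              threshold = 0.05) {
  mode <- match.arg(mode)
  s <- first_sigmoid
  if (mode == "tangent") {
    slope_t <- (s$A2 - s$A1) / (4 * s$dT)
    mid <- (s$A1 + s$A2) / 2
    b <- low_plateau$slope; a <- low_plateau$intercept
    if (abs(b - slope_t) < 1e-12 * max(1, abs(slope_t)))
      stopf("plateau line is parallel to the sigmoid tangent; onset undefined",
            class = "mabtherm_onset_error")
    (mid - slope_t * s$T0 - a) / (b - slope_t)
  } else {
    tv <- get_tv(curve)
    amp <- s$A2 - s$A1
    target <- s$A1 + threshold * amp
    u <- (tv$v - s$A1) / amp          # progress along the first transition
    cross <- which(u[-1L] >= threshold & u[-length(u)] < threshold)
    if (!length(cross))
      stopf("curve never exceeds the %g amplitude threshold", threshold,
            class = "mabtherm_onset_error")
    i <- cross[1L]
    t1 <- tv$t[i]; t2 <- tv$t[i + 1L]
    v1 <- tv$v[i]; v2 <- tv$v[i + 1L]
    if (v2 == v1) return(t1)
    t1 + (target - v1) / (v2 - v1) * (t2 - t1)
  }
}
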