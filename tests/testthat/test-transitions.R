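test_that("plateau detection finds the flats of constructed curves", {
  ## flat - steep rise - flat
  tt <- 1:60
  vv <- c(rep(0, 25), seq(0.04, 0.96, length.out = 10), rep(1, 25))
  pl <- detect_plateaus(beta_fraction_curve(tt, vv))
  expect_length(pl, 2L)
  expect_lte(pl[[1]]$T_range[2], 26)
  expect_gte(pl[[2]]$T_range[1], 35)
  expect_lt(abs(pl[[1]]$slope), 0.02)

  ## pure noiseless sigmoid with asymptotes inside the data: both tails
  spec <- single_vh_spec()
  cv <- rescale_unit_interval(fraction_peak_referenced(generate_cd_signal(spec)))
  pl2 <- detect_plateaus(cv)
  expect_gte(length(pl2), 2L)
  expect_lt(pl2[[1]]$T_range[2], 70)
  expect_gt(pl2[[length(pl2)]]$T_range[1], 80)

  ## globally linear data: one plateau covering everything (fallback)
  line <- beta_fraction_curve(1:30, 0.05 * (1:30))
  pl3 <- detect_plateaus(line)
  expect_length(pl3, 1L)
  expect_equal(pl3[[1]]$n_points, 30L)

  expect_error(detect_plateaus(beta_fraction_curve(1:6, c(0, .2, .4, .6, .8, 1))),
               class = "mabtherm_segmentation_error")  # < 2 min_points pts
})

test_that("Boltzmann fits recover parameters and satisfy the midpoint identity", {
  tt <- seq(60, 95, by = 0.5)
  truth <- c(A1 = 0, A2 = 1, T0 = 77, dT = 1.5)
  set.seed(42)
  y <- boltzmann_eval(tt, 0, 1, 77, 1.5) + rnorm(length(tt), 0, 0.005)
  fit <- fit_boltzmann(tt, y)
  expect_lt(abs(fit$T0 - 77), 0.1)
  expect_lt(abs(fit$dT - 1.5), 0.15)
  ## f(T0) = (A1 + A2)/2 for the fitted curve, by the model's closed form
  expect_equal(predict(fit, fit$T0), (fit$A1 + fit$A2) / 2, tolerance = 1e-12)
  ## rmse equals sqrt(RSS/n) recomputed from residuals
  res <- y - predict(fit, tt)
  expect_equal(fit$rmse, sqrt(sum(res^2) / length(res)), tolerance = 1e-10)
})

test_that("the sigmoid chain recovers a three-transition melt in order", {
  fit <- melt_fit(generate_cd_signal(melt_preset("f1il-like", noise_sd = 0)))
  expect_length(fit$sigmoids, 3L)
  expect_equal(fit$T_m, c(52.4, 67.5, 86.8), tolerance = 0.01)  # relative
  expect_true(all(diff(fit$T_m) > 0))
  ## falling third region: A1 > A2
  s3 <- fit$sigmoids[[3]]
  expect_gt(s3$A1, s3$A2)
})

test_that("shape-model selection minimises RMSE with a parsimony tie-break", {
  tt <- seq(25, 97, by = 1)
  ## symmetric Gaussian data: gaussian and bigaussian tie; fewer params win
  g <- 0.2 + 0.7 * exp(-(tt - 60)^2 / (2 * 12^2))
  sh <- fit_shape_models(beta_fraction_curve(tt, g))
  expect_equal(sh$kind, "gaussian")
  expect_lt(sh$rmse, 1e-8)   # perfect fit has RMSE ~ 0

  ## asymmetric data: bi-Gaussian wins
  s12 <- ifelse(tt <= 60, 5, 15)
  bg <- 0.1 + 0.8 * exp(-(tt - 60)^2 / (2 * s12^2))
  set.seed(7)
  bgn <- bg + rnorm(length(tt), 0, 0.005)
  sh2 <- fit_shape_models(beta_fraction_curve(tt, bgn))
  expect_equal(sh2$kind, "bigaussian")
  expect_lt(abs(sh2$params$sigma1 - 5), 1)
  expect_lt(abs(sh2$params$sigma2 - 15), 2)

  ## every candidate's RMSE equals sqrt(RSS/n) by construction
  cr <- attr(sh2, "candidate_rmse")
  expect_true(all(c("parabolic", "gaussian", "bigaussian") %in% names(cr)))
  expect_equal(unname(cr["bigaussian"]), sqrt(sh2$rss / length(tt)))
})

test_that("intersection temperatures match symmetry and a numeric oracle", {
  mk <- function(A1, A2, T0, dT)
    structure(list(A1 = A1, A2 = A2, T0 = T0, dT = dT,
                   fit_T_range = c(T0 - 15, T0 + 15)),
              class = "boltzmann_fit")
  ## mirror pair about T = 70 with equal spans crosses exactly at 70
  s1 <- mk(0, 1, 65, 2); s2 <- mk(1, 0, 75, 2)
  expect_equal(intersection_temperature(s1, s2), 70, tolerance = 1e-8)

  ## analytically solvable crossing vs high-precision root as oracle
  a <- mk(0, 0.6, 60, 3); b <- mk(0.55, 1.2, 80, 1.8)
  g <- function(T) boltzmann_eval(T, a$A1, a$A2, a$T0, a$dT) -
                   boltzmann_eval(T, b$A1, b$A2, b$T0, b$dT)
  oracle <- uniroot(g, c(64, 74), tol = 1e-13)$root
  expect_equal(intersection_temperature(a, b), oracle, tolerance = 1e-8)

  ## identical sigmoids never cross
  expect_error(intersection_temperature(mk(0, 1, 60, 2), mk(0, 1, 70, 2)),
               class = "mabtherm_intersection_error")
  expect_error(intersection_temperature(s2, s1),
               class = "mabtherm_validation_error")
})

test_that("onset temperature follows the tangent construction closed form", {
  ## flat plateau at f = 0 and a Boltzmann: T_onset = T0 - 2 dT analytically
  s <- structure(list(A1 = 0, A2 = 1, T0 = 77, dT = 1.5,
                      fit_T_range = c(60, 95)), class = "boltzmann_fit")
  pl <- structure(list(T_range = c(25, 60), slope = 0, intercept = 0,
                       r_squared = 1, n_points = 36), class = "plateau")
  expect_equal(onset_temperature(NULL, s, pl), 77 - 2 * 1.5, tolerance = 1e-10)

  ## plateau parallel to the tangent -> onset undefined
  par_pl <- structure(list(T_range = c(25, 60), slope = 1 / (4 * 1.5),
                           intercept = 0, r_squared = 1, n_points = 36),
                      class = "plateau")
  expect_error(onset_temperature(NULL, s, par_pl),
               class = "mabtherm_onset_error")

  ## threshold mode: linear interpolation between grid points
  tt <- seq(60, 95, by = 1)
  cv <- beta_fraction_curve(tt, boltzmann_eval(tt, 0, 1, 77, 1.5))
  t5 <- onset_temperature(cv, s, pl, mode = "threshold", threshold = 0.05)
  ## oracle: solve f(T) = 0.05 for the Boltzmann
  oracle <- 77 + 1.5 * log(0.05 / 0.95)
  expect_lt(abs(t5 - oracle), 0.1)
})

test_that("segmentation of the temperature-mirrored curve mirrors T_m", {
  spec <- melt_preset("f1il-like", noise_sd = 0)
  sig <- generate_cd_signal(spec)
  cv <- rescale_unit_interval(fraction_peak_referenced(sig))
  mirrored <- beta_fraction_curve(sort(2 * 61 - cv$temperatures), rev(cv$f),
                                  mode = "peak_referenced")
  pl_f <- detect_plateaus(cv); pl_m <- detect_plateaus(mirrored)
  sg_f <- fit_sigmoid_chain(cv, pl_f, fit_shape_models(cv))
  sg_m <- fit_sigmoid_chain(mirrored, pl_m, fit_shape_models(mirrored))
  tm_f <- sort(vapply(sg_f, `[[`, numeric(1), "T0"))
  tm_m <- sort(122 - vapply(sg_m, `[[`, numeric(1), "T0"))
  expect_equal(length(tm_f), length(tm_m))
  expect_equal(tm_f, tm_m, tolerance = 0.02)  # relative on ~50-90 degC
})
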