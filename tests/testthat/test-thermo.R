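test_that("equilibrium constant and Gibbs energy follow the two-state forms", {
  expect_equal(equilibrium_constant(0.5), 1)
  expect_equal(equilibrium_constant(0.75), 3)
  expect_equal(equilibrium_constant(0.9), 9, tolerance = 1e-12)
  expect_error(equilibrium_constant(0), class = "mabtherm_domain_error")
  expect_error(equilibrium_constant(1), class = "mabtherm_domain_error")

  expect_equal(gibbs(1, 25), 0)
  expect_equal(gibbs(exp(1), 25), -8.314 * 298.15 / 1000, tolerance = 1e-12)
  ## antisymmetry in ln K
  expect_equal(gibbs(1 / exp(1), 25), -gibbs(exp(1), 25))
  expect_error(gibbs(-1, 25), class = "mabtherm_domain_error")
})

test_that("the linear transition fit reports the Celsius-axis quantities", {
  tt <- seq(73, 81, by = 0.5)
  lt <- linear_transition_fit(tt, 100 - 1.3 * tt, window = 1e6)
  expect_equal(lt$T_m, 100 / 1.3, tolerance = 1e-9)
  expect_equal(lt$dS, 1300, tolerance = 1e-9)
  expect_equal(lt$dH_paper, 100, tolerance = 1e-9)
  ## the two conventions derive from one regression
  expect_equal(lt$dH_vH, 1.3 * (100 / 1.3 + 273.15), tolerance = 1e-9)

  expect_error(linear_transition_fit(tt, rep(10, length(tt))),
               class = "mabtherm_fit_error")   # no in-window points
  expect_error(linear_transition_fit(c(74, 75, 76), rep(0.1, 3)),
               class = "mabtherm_fit_error")   # dS ~ 0, no crossing
})

test_that("dH = T_m(degC) x dS holds identically for every fitted region", {
  for (preset in c("f1il-like", "water-like")) {
    fit <- melt_fit(generate_cd_signal(melt_preset(preset, seed = 3)))
    for (r in fit$regions) {
      expect_equal(r$dH_paper, r$T_m * r$dS / 1000, tolerance = 1e-9)
      expect_equal(r$dH_vH, (r$T_m + 273.15) * r$dS / 1000, tolerance = 1e-9)
      ## dG at the fitted root is zero: evaluate the fitted line at T_m
      expect_lt(abs(r$dH_paper - r$T_m * r$dS / 1000), 1e-9)
    }
  }
})

test_that("region fractions span [0,1] over their own region only", {
  fit <- melt_fit(generate_cd_signal(melt_preset("f1il-like", noise_sd = 0)))
  r2 <- fit$regions[[2]]
  expect_gt(min(r2$curve$f_i), 0)
  expect_lt(max(r2$curve$f_i), 1)
  expect_true(all(r2$curve$T >= fit$sigmoids[[2]]$fit_T_range[1]))
  expect_true(all(r2$curve$T <= fit$sigmoids[[2]]$fit_T_range[2]))
  ## K = 1 exactly where f crosses 0.5 (interpolated through the fit)
  expect_equal(r2$curve$K[which.min(abs(r2$curve$f_i - 0.5))],
               equilibrium_constant(r2$curve$f_i[which.min(abs(r2$curve$f_i - 0.5))]))
})

test_that("region_fraction consistency: whole-curve region equals the global fraction", {
  spec <- single_vh_spec()
  truth <- generate_fraction_curve(spec)
  cv <- beta_fraction_curve(spec$T_grid, truth$f_true)
  s <- structure(list(A1 = 0, A2 = 1, T0 = 75.5, dT = 2.35,
                      fit_T_range = range(spec$T_grid)),
                 class = "boltzmann_fit")
  rf <- region_fraction(cv, s, low_ref = 0, high_ref = 1)
  expect_equal(rf$f_i, truth$f_true, tolerance = 1e-12)
  expect_error(region_fraction(cv, s, low_ref = 0.5, high_ref = 0.5),
               class = "mabtherm_degenerate_error")
})

test_that("totals sum regions and evaluate dG at the reference temperature", {
  mk <- function(dH, dS) structure(
    list(index = 1L, dH_paper = dH, dS = dS,
         se = c(T_m = 0.1, dS = 20, dH_paper = 1)),
    class = "region_thermo")
  ## single region, T_ref = T_m -> dG_total = 0
  one <- mk(120, 1560)
  t1 <- totals(list(one), T_ref = 120 / 1.56)
  expect_equal(t1$dG_total, 0, tolerance = 1e-9)

  ## F2IL printed regions: 53 + 134 + 73 = 260 kJ/mol
  f2il <- list(mk(53, 1050), mk(134, 2120), mk(73, 870))
  t2 <- totals(f2il, T_I = c(59.4, 73.1))
  expect_equal(t2$dH_total, 260)
  expect_equal(t2$dS_total, 4040)
  expect_equal(t2$T_ref, 73.1)   # last intersection rule

  expect_error(totals(list()), class = "mabtherm_validation_error")
})

test_that("noisy single-transition melts recover T_m and dS reliably", {
  ## sigma_f = 1% of span, 73-point 25-97 degC grid; the transition sits
  ## centrally so both pre- and post-transition baselines are determined
  ## from ample points (a transition crowding the grid edge starves one
  ## baseline window and is exercised elsewhere)
  n_ok <- 0L; n <- 40L
  for (s in seq_len(n)) {
    spec <- single_vh_spec(T_m = 60, dH_vH = 400000, noise_sd = 33.8,
                           seed = 1000 + s)
    fit <- tryCatch(suppressWarnings(melt_fit(generate_cd_signal(spec))),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$regions) != 1L) next
    ok_tm <- abs(fit$T_m[1] - 60) < 0.5
    ok_ds <- abs(fit$regions[[1]]$dS / (400000 / 333.15) - 1) < 0.1
    if (ok_tm && ok_ds) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, ceiling(0.95 * n))
})

test_that("excluding extreme fractions barely moves T_m on clean data", {
  fit1 <- melt_fit(generate_cd_signal(single_vh_spec()))
  fit2 <- melt_fit(generate_cd_signal(single_vh_spec()),
                   control = melt_control(epsilon_f = 0.10))
  r1 <- fit1$regions[[1]]; r2 <- fit2$regions[[1]]
  expect_lt(abs(r1$T_m - r2$T_m), max(r1$se[["T_m"]], 0.05))
})
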