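test_that("baseline fitting recovers exact lines and reports r-squared", {
  sig <- melt_signal(25:40, 2 + 0.1 * (25:40))
  b <- fit_baseline(sig, c(25, 40), "low_T")
  expect_equal(b$intercept, 2, tolerance = 1e-10)
  expect_equal(b$slope, 0.1, tolerance = 1e-10)
  expect_equal(b$r_squared, 1)

  flat <- fit_baseline(melt_signal(25:40, rep(3, 16)), c(25, 40), "high_T")
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  expect_error(fit_baseline(sig, c(25, 26.5), "low_T"),
               class = "mabtherm_fit_error")  # 2-point range
})

test_that("two-state fraction satisfies its boundary conditions", {
  tt <- 25:97
  low <- structure(list(intercept = -3000, slope = 2, T_range = c(25, 40),
                        which = "low_T", r_squared = 1, n = 16),
                   class = "baseline_fit")
  high <- structure(list(intercept = -6500, slope = 4, T_range = c(85, 97),
                         which = "high_T", r_squared = 1, n = 13),
                    class = "baseline_fit")
  y0 <- -3000 + 2 * tt; ymax <- -6500 + 4 * tt

  f0 <- fraction_two_state(melt_signal(tt, y0), low, high)
  expect_equal(f0$f, rep(0, length(tt)), tolerance = 1e-12)

  fmid <- fraction_two_state(melt_signal(tt, (y0 + ymax) / 2), low, high)
  expect_equal(fmid$f, rep(0.5, length(tt)), tolerance = 1e-12)

  ## synthetic forward model inverts pointwise
  spec <- single_vh_spec()
  truth <- generate_fraction_curve(spec)
  sig <- generate_cd_signal(spec, truth)
  f <- fraction_two_state(sig, low, high)
  expect_equal(f$f, truth$f_true, tolerance = 1e-10)

  ## crossing baselines -> degenerate denominator names the temperature
  badhigh <- structure(list(intercept = -3000, slope = 2, T_range = c(85, 97),
                            which = "high_T", r_squared = 1, n = 13),
                       class = "baseline_fit")
  expect_error(fraction_two_state(sig, low, badhigh),
               class = "mabtherm_degenerate_error")
})

test_that("peak-referenced fraction handles monotone and rise-fall signals", {
  tt <- 25:97
  mono <- melt_signal(tt, seq(-1, -10, length.out = length(tt)))
  f <- fraction_peak_referenced(mono)
  expect_equal(f$f[1], 0)
  expect_equal(f$f[length(tt)], 1)
  expect_true(all(diff(f$f) > 0))

  ## V-shape: f rises to 1 at the internal extremum then falls
  vsig <- melt_signal(tt, -10 * exp(-(tt - 60)^2 / 200) - 1)
  fv <- fraction_peak_referenced(vsig)
  expect_equal(max(fv$f), 1)
  expect_equal(tt[which.max(fv$f)], 60)
  expect_lt(fv$f[length(tt)], 0.5)

  expect_error(fraction_peak_referenced(melt_signal(tt, rep(3, length(tt)))),
               class = "mabtherm_degenerate_error")
})

test_that("unit-interval rescaling is the exact affine map and idempotent", {
  cv <- beta_fraction_curve(1:3, c(0.2, 0.5, 0.4))
  out <- rescale_unit_interval(cv)
  expect_equal(out$f, c(0, 1, 2 / 3))
  expect_identical(rescale_unit_interval(out)$f, out$f)

  cv2 <- beta_fraction_curve(1:5, c(0.1, 0.3, 0.9, 0.6, 0.2))
  r2 <- rescale_unit_interval(cv2)
  expect_equal(range(r2$f), c(0, 1))
  expect_error(rescale_unit_interval(beta_fraction_curve(1:3, rep(1, 3))),
               class = "mabtherm_degenerate_error")
})

test_that("the fraction is invariant under affine transforms of the raw signal", {
  spec <- single_vh_spec(noise_sd = 30, seed = 4)
  sig <- generate_cd_signal(spec)
  for (ab in list(c(2, 0), c(-1.5, 300), c(0.1, -40))) {
    sig2 <- sig
    sig2$y <- ab[1] * sig$y + ab[2]
    w_lo <- c(25, 40); w_hi <- c(88, 97)
    f1 <- fraction_two_state(sig,
                             fit_baseline(sig, w_lo, "low_T"),
                             fit_baseline(sig, w_hi, "high_T"))
    f2 <- fraction_two_state(sig2,
                             fit_baseline(sig2, w_lo, "low_T"),
                             fit_baseline(sig2, w_hi, "high_T"))
    expect_equal(f2$f, f1$f, tolerance = 1e-9)
  }
})

test_that("mode selection separates sigmoidal from rise-fall signals", {
  expect_equal(select_fraction_mode(generate_cd_signal(single_vh_spec())),
               "two_state")
  expect_equal(select_fraction_mode(
    generate_cd_signal(melt_preset("f1il-like", noise_sd = 0))),
    "peak_referenced")
  expect_equal(select_fraction_mode(
    generate_cd_signal(melt_preset("water-like", noise_sd = 0))),
    "peak_referenced")
})
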