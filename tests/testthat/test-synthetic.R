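test_that("the forward fraction model hits its van't Hoff anchor points", {
  spec <- melt_preset("f1il-like", noise_sd = 0)
  truth <- generate_fraction_curve(spec)
  ## p_i = 0.5 exactly at each T_m: f there equals the mean of the
  ## surrounding levels plus the other transitions' occupancies
  for (tr in spec$transitions) {
    TK <- tr$T_m + 273.15
    K <- exp(-(tr$dH_vH / 8.314) * (1 / TK - 1 / TK))
    expect_equal(K / (1 + K), 0.5)
  }
  ## single transition limits
  s1 <- single_vh_spec()
  f1 <- generate_fraction_curve(s1)
  expect_lt(f1$f_true[1], 1e-6)
  expect_gt(f1$f_true[nrow(f1)], 0.999)

  ## two opposing transitions produce an interior maximum at the root of df/dT
  rise_fall <- melt_spec(list(
    transition_spec(50, 4e5, 0, 1), transition_spec(70, 4e5, 1, 0)))
  frf <- generate_fraction_curve(rise_fall)
  peak_idx <- which.max(frf$f_true)
  expect_true(peak_idx > 1 && peak_idx < nrow(frf))
  ## numeric root of the analytic derivative as oracle for the peak
  dfdT <- function(T) {
    v <- 0
    for (tr in rise_fall$transitions) {
      TK <- T + 273.15; TmK <- tr$T_m + 273.15
      K <- exp(-(tr$dH_vH / 8.314) * (1 / TK - 1 / TmK))
      p <- K / (1 + K)
      v <- v + (tr$f_end - tr$f_start) * p * (1 - p) * tr$dH_vH / (8.314 * TK^2)
    }
    v
  }
  oracle <- uniroot(dfdT, c(55, 65), tol = 1e-10)$root
  expect_lt(abs(frf$T[peak_idx] - oracle), 1)   # grid resolution
})

test_that("the signal generator is seeded, exact at zero noise, and validated", {
  spec <- single_vh_spec()
  truth <- generate_fraction_curve(spec)
  sig <- generate_cd_signal(spec)
  y0 <- spec$baseline_low[1] + spec$baseline_low[2] * spec$T_grid
  ym <- spec$baseline_high[1] + spec$baseline_high[2] * spec$T_grid
  expect_equal(sig$y, y0 + (ym - y0) * truth$f_true, tolerance = 1e-12)

  noisy <- melt_preset("f1il-like", seed = 99)
  expect_identical(generate_cd_signal(noisy)$y, generate_cd_signal(noisy)$y)
  noisy2 <- melt_preset("f1il-like", seed = 100)
  expect_false(identical(generate_cd_signal(noisy)$y,
                         generate_cd_signal(noisy2)$y))

  crossing <- melt_spec(list(transition_spec(60, 4e5)),
                        baseline_low = c(-3000, 2),
                        baseline_high = c(-3500, 10))
  expect_error(generate_cd_signal(crossing),
               class = "mabtherm_validation_error")
})

test_that("full spectra embed the melt signal at 218 nm with the right band signs", {
  spec <- melt_preset("f1il-like", noise_sd = 0)
  ser <- generate_full_spectra(spec)
  expect_equal(extract_wavelength(ser, 218)$y, generate_cd_signal(spec)$y,
               tolerance = 1e-9)
  ## negative beta-sheet band at 218, positive beta-turn band at 202
  mid <- nrow(ser$signal) %/% 2
  expect_lt(ser$signal[mid, which(ser$wavelengths == 218)], 0)
  expect_gt(ser$signal[mid, which(ser$wavelengths == 202)], 0)

  ## zeroing the 250-260 nm window barely moves the 218 nm band
  z <- zero_high_wavelength(ser, c(250, 260))
  rel <- max(abs(z$signal[, 29] - ser$signal[, 29])) /
    max(abs(ser$signal[, 29]))
  expect_lt(rel, 0.02)
})

test_that("sensorgram generation is seeded and reduces to the simulator", {
  clean <- generate_sensorgram(bli_truth, bli_C)
  sim <- do.call(simulate_1to2, c(bli_truth, list(C = bli_C)))
  expect_identical(clean$R, sim$R)
  a <- generate_sensorgram(bli_truth, bli_C, noise_sd = 0.01, seed = 5)
  b <- generate_sensorgram(bli_truth, bli_C, noise_sd = 0.01, seed = 5)
  expect_identical(a$R, b$R)
  d <- generate_sensorgram(bli_truth, bli_C, drift = 1e-4)
  expect_equal(d$R - clean$R, 1e-4 * clean$t, tolerance = 1e-12)
})

test_that("melt specs validate ordering and ranges", {
  expect_error(melt_spec(list(transition_spec(70, 4e5),
                              transition_spec(50, 4e5))),
               class = "mabtherm_validation_error")
  expect_error(transition_spec(50, -1), class = "mabtherm_validation_error")
  expect_error(transition_spec(50, 4e5, f_start = 1.2),
               class = "mabtherm_validation_error")
  ## out-of-[0,1] overlap warns rather than errors
  overlap <- melt_spec(list(transition_spec(50, 3e5, 0, 0.9),
                            transition_spec(55, 3e5, 0.5, 1)))
  expect_warning(generate_fraction_curve(overlap), "overlapping")
})
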