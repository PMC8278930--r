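test_that("background subtraction is element-wise and validates the grid", {
  ser <- toy_series()
  ## background equal to the first row zeroes that row
  out <- subtract_background(ser, ser$signal[1, ])
  expect_equal(out$signal[1, ], c(`200` = 0, `218` = 0, `250` = 0),
               ignore_attr = TRUE)
  ## zero background is the identity
  expect_equal(subtract_background(ser, rep(0, 3))$signal, ser$signal)
  ## replicate averaging happens before subtraction
  reps <- rbind(ser$signal[1, ] + 1, ser$signal[1, ] - 1)
  expect_equal(subtract_background(ser, average_background(reps))$signal[1, ],
               rep(0, 3), ignore_attr = TRUE)
  ## wrong grid
  expect_error(subtract_background(ser, rep(0, 4)),
               class = "mabtherm_validation_error")
})

test_that("high-wavelength zeroing removes per-temperature offsets and is idempotent", {
  ser <- series_from_fn(function(T, wl) ifelse(T == 25, 1, -1) + 0 * wl,
                        temperatures = c(25, 50))
  out <- zero_high_wavelength(ser, c(250, 260))
  expect_equal(max(abs(out$signal)), 0)

  ## offsets removed independently per temperature on a 4-point toy spectrum:
  ## rows (+1 everywhere) and (-1 everywhere) both become flat zero
  toy <- cd_spectrum_series(c(25, 30), c(248, 250, 255, 260),
                            rbind(c(5, 1, 1, 1), c(-3, -1, -1, -1)))
  z <- zero_high_wavelength(toy, c(250, 260))
  expect_equal(z$signal, rbind(c(4, 0, 0, 0), c(-2, 0, 0, 0)),
               ignore_attr = TRUE)

  ## idempotent; already-zero-mean window unchanged
  expect_equal(zero_high_wavelength(z, c(250, 260))$signal, z$signal)
  expect_error(zero_high_wavelength(toy, c(100, 101)),
               class = "mabtherm_validation_error")
})

test_that("Savitzky-Golay filter is exact on polynomials up to its order", {
  wl <- 190:260
  for (deg in c(0, 3, 5)) {
    ser <- series_from_fn(function(T, l) (l - 220)^deg / 100^deg,
                          temperatures = c(25, 50))
    sm <- savitzky_golay_smooth(ser, 7, 5)
    expect_equal(sm$signal, ser$signal, tolerance = 1e-10)
  }
  expect_error(savitzky_golay_smooth(toy_series(), 7, 5),
               class = "mabtherm_validation_error")  # window > grid
})

test_that("interior spike response equals the closed-form SG centre weight", {
  wl <- 190:260
  sig <- matrix(0, 1, length(wl))
  j <- 30L; h <- 5
  sig[1, j] <- h
  ser <- cd_spectrum_series(25, wl, sig)
  sm <- savitzky_golay_smooth(ser, 7, 5)
  ## oracle: brute-force least squares of an order-5 polynomial on the
  ## 7-point window centred at the spike, evaluated at the centre
  X <- outer(-3:3, 0:5, `^`)
  w_centre <- (X %*% solve(crossprod(X), t(X)))[4, 4]
  expect_equal(sm$signal[1, j], w_centre * h, tolerance = 1e-10)
})

test_that("MRE conversion follows the MRW formula and is linear", {
  ## hand evaluation: MRE = -10 x (110000/1000) / (10 x 0.01 x 100) = -110
  meta <- sample_meta(100, 0.01, 110000, 1001)
  sig <- melt_signal(c(25, 26), c(-10, -10), units = "millidegrees")
  out <- to_mre(sig, meta)
  expect_equal(out$y, c(-110, -110))
  expect_equal(out$units, "MRE")

  ## theta = 0 -> 0; doubling concentration halves MRE
  expect_equal(to_mre(melt_signal(25:26, c(0, 0), units = "millidegrees"),
                      meta)$y, c(0, 0))
  meta2 <- sample_meta(200, 0.01, 110000, 1001)
  expect_equal(to_mre(sig, meta2)$y, out$y / 2)

  ## linearity in theta
  sig3 <- melt_signal(c(25, 26), c(-4, 6), units = "millidegrees")
  expect_equal(to_mre(sig3, meta)$y,
               to_mre(melt_signal(c(25, 26), c(-2, 3),
                                  units = "millidegrees"), meta)$y * 2)

  ## refuses double conversion
  expect_error(to_mre(out, meta), class = "mabtherm_validation_error")
})

test_that("the preprocessing pipeline is ordered and bit-reproducible", {
  spec <- melt_preset("f1il-like", seed = 11)
  ser <- generate_full_spectra(spec)
  ser$units <- "millidegrees"
  ser$meta <- default_meta()
  cfg <- preprocess_config()
  a <- preprocess_cd(ser, cfg)
  b <- preprocess_cd(ser, cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(attr(a, "preprocess_steps"), c("zero", "sg_wavelength", "mre"))
  expect_equal(a$units, "MRE")
  ## zeroing post-condition holds on the result
  idx <- a$wavelengths >= 250 & a$wavelengths <= 260
  ## (zeroing precedes smoothing/MRE, both of which preserve a zero window
  ## mean only approximately at the edge; check the dedicated step instead)
  z <- zero_high_wavelength(ser, cfg$zero_window)
  expect_lt(max(abs(rowMeans(z$signal[, idx]))), 1e-9)
})

test_that("preprocess_config validates its invariants", {
  expect_error(preprocess_config(sg_window = 6),
               class = "mabtherm_validation_error")
  expect_error(preprocess_config(sg_window = 5, sg_order = 5),
               class = "mabtherm_validation_error")
  expect_error(preprocess_config(zero_window = c(260, 250)),
               class = "mabtherm_validation_error")
})
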