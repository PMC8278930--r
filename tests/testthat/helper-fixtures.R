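## shared fixture builders (everything is generated in code; no data files)

toy_series <- function(temperatures = c(25, 27),
                       wavelengths = c(200, 218, 250),
                       signal = matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
                                       byrow = TRUE),
                       units = "millidegrees") {
  cd_spectrum_series(temperatures, wavelengths, signal, units = units)
}

default_meta <- function() sample_meta(1, 0.1, 146000, 1320, label = "toy")

## a wide wavelength grid series built from a function of (T, lambda)
series_from_fn <- function(fn, temperatures = c(25, 50, 75),
                           wavelengths = 190:260, units = "millidegrees") {
  sig <- outer(temperatures, wavelengths, fn)
  cd_spectrum_series(temperatures, wavelengths, sig, units = units)
}

single_vh_spec <- function(T_m = 75.5, dH_vH = 430000, noise_sd = 0,
                           seed = NULL)
  melt_spec(list(transition_spec(T_m, dH_vH)), noise_sd = noise_sd,
            seed = seed)

## canonical 1:2 parallel-sites truth used across BLI tests
bli_truth <- list(kon1 = 2e5, koff1 = 5e-4, Rmax1 = 0.8,
                  kon2 = 1e4, koff2 = 5e-3, Rmax2 = 0.4)
bli_C <- mass_to_molar(0.96, 146000)
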