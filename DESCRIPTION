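Package: mabtherm
Title: Thermal Unfolding Thermodynamics and Binding Kinetics of Antibody
    Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of variable-temperature circular dichroism (CD) melt
    data and bio-layer interferometry (BLI) sensorgrams for antibody
    formulations.  Converts temperature-resolved CD spectra into a relative
    beta-sheet-fraction melt curve, segments the curve into linear plateaus
    and Boltzmann sigmoid transition regions, extracts midpoint and
    intersection temperatures, and derives per-region van't Hoff
    thermodynamics (equilibrium constant, Gibbs energy, enthalpy, entropy)
    together with their totals.  Also simulates and fits BLI sensorgrams
    under 1:1 and bivalent 1:2 binding models, reporting rate constants and
    equilibrium dissociation constants.  Includes a seeded synthetic-data
    generator for melt curves and sensorgrams providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
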