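---
title: "Methods: beta-sheet melt-curve thermodynamics and bivalent BLI kinetics"
author: "mabtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-sheet melt-curve thermodynamics and bivalent BLI kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Antibody formulations are screened for thermal stability by
variable-temperature circular dichroism (CD). The negative far-UV band near
218 nm reports beta-sheet content; as an IgG is heated from 25 to 97 °C its
218 nm signal traces out one to three sequential conformational transitions,
each well described by a two-state equilibrium. `mabtherm` turns such a
melt series into:

* a **relative beta-sheet fraction** curve `f(T)` scaled onto [0, 1];
* a **segmentation** into `m` linear plateaus and `r` Boltzmann sigmoid
  transition regions, with midpoints `T_m`, inter-region intersection
  temperatures `T_I`, and an onset temperature `T_onset`;
* **per-region two-state thermodynamics**: `K = f/(1-f)`,
  `ΔG = -RT ln K`, and a linear fit of `ΔG` against temperature in the
  transition window giving `ΔH`, `ΔS` and their totals;
* **BLI binding kinetics** under 1:1 and bivalent 1:2 models with
  `K_D = koff/kon`.

The package is built around two classed fitting functions, `melt_fit()` and
`bli_fit()`, with the usual `print`/`summary`/`coef`/`predict`/`plot`/
`residuals` methods, plus a seeded synthetic-data generator
(`melt_preset()`, `generate_cd_signal()`, `generate_sensorgram()`) that
provides ground truth for every stage.

## Spectral preprocessing

Raw ellipticity matrices (temperature × wavelength, millidegrees) are
treated in a fixed order: averaged-background subtraction, zeroing against
the featureless 250–260 nm window (per temperature, so the window mean is
exactly zero), Savitzky–Golay smoothing along the wavelength axis with a
7-point window of polynomial order 5, and conversion to mean residue
ellipticity

MRE = θ(mdeg) · MRW / (10 · l(cm) · c(mg/mL)),  MRW = MW / (n_res − 1).

The MRE formula is the standard mean-residue-weight convention; every
downstream quantity is a *relative* fraction and therefore invariant to any
fixed linear rescaling of the signal, so this convention cannot change the
thermodynamic outputs. Savitzky–Golay edge points are the fitted polynomial
of the first/last full window evaluated at the edge — no padding, no
fabricated data outside 190–260 nm; polynomials of degree ≤ 5 pass through
the filter unchanged. Missing matrix cells are rejected rather than
imputed, because a 7-point smoother is not defined across gaps. Smoothing
along the temperature axis is available but off by default: the instrument
ramp is slow and monotone, and smoothing across transitions would bias the
widths that the thermodynamics are computed from.

## From signal to fraction

Two referencing modes implement `f = (y − y0)/(ymax − y0)`:

* **two_state** (monotone melts): `y0(T)` and `ymax(T)` are lines fitted to
  the low- and high-temperature plateaus of the raw signal. Automatic
  window choice takes the detected tail plateaus, then a refinement pass
  re-fits both lines on points at least 8 sigmoid widths away from the
  outermost fitted midpoints (falling back to 6 or 4 widths if too few
  points remain). Without the refinement the windows include transition
  tails and the resulting baseline tilt biases `T_m` and `ΔS` by ~1%.
* **peak_referenced** (rise-then-fall melts): constants, `y0` the
  minimum-magnitude endpoint signal and `ymax` the strongest (most
  negative) signal, so `f = 1` at the beta-sheet maximum.

Mode selection mirrors minimum-RMSE model trialling: a Boltzmann sigmoid
and a bi-Gaussian are fitted to the raw `y(T)`; `peak_referenced` is chosen
only when the bi-Gaussian both wins on RMSE *and* places its peak in the
interior of the temperature range — for monotone data the best bi-Gaussian
drifts its centre to the boundary, and that degenerate win must not trigger
constant referencing. The curve is finally rescaled affinely onto [0, 1]
(idempotent). `f` is computed on the signed signal throughout; the sign
lives in the referencing constants.

## Segmentation

**Plateau detection** (the published objective is "maximise r² of the
linear fit"; the algorithm is ours): seed 5-point windows at both data ends
and at local minima of a coarse smoothed derivative, grow each window
point-by-point while the window's least-squares line keeps
`|slope| ≤ slope_tol` and an RMSE below a cap, and merge overlapping
windows when their union still qualifies. Two numerical choices matter:

* the RMSE cap is `max(2·σ̂, 0.005·range)`, where `σ̂` is a robust noise
  scale from the *lower quartile* of successive differences (the median is
  inflated by transition structure, and a flat noisy plateau has r² ≈ 0,
  so a pure r² rule cannot accept genuine plateaus). The 0.005·range floor
  admits the gently curved quasi-plateaus that sit between closely spaced
  transitions even on noiseless data;
* points whose coarse derivative exceeds `1.5·slope_tol` are blocked from
  joining any plateau, which is what actually stops windows creeping
  across a transition flank.

`slope_tol` defaults to 0.02 fraction-units/°C. With transition entropies
of ~900–2200 J K⁻¹ mol⁻¹ (widths ≈ 1.3–3 °C) and midpoint gaps of ~15 °C,
the true inter-transition slope of `f` never falls below ~0.01 /°C, while
transition flanks run 0.04–0.2 /°C, so 0.02 separates the two regimes; a
much smaller tolerance admits no interior plateau at all. A globally linear
data set is returned as a single full-range plateau (fallback) rather than
an error.

**Sigmoid chain.** One Boltzmann sigmoid
`f(T) = A2 + (A1 − A2)/(1 + exp((T − T0)/dT))` is least-squares fitted over
each span between sequential plateaus (plateau points included at both
ends); when the overall shape model is (bi-)Gaussian and data continue past
the last plateau, a final sigmoid runs from the last plateau to the
minimum of the fitted shape model. Fits use Levenberg–Marquardt with
deterministic initialisation (asymptotes from span endpoints, midpoint from
the maximum smoothed derivative, width from a tenth of the span) and no
random restarts. The optimiser runs unbounded — `nls.lm`'s bounded mode
loses its automatic parameter scaling and stalls on badly scaled problems —
and the exact symmetry `(A1, A2, dT) ↔ (A2, A1, −dT)` is canonicalised to
`dT > 0` afterwards.

For multi-transition curves a **joint staircase refinement** follows: the
whole curve is re-fitted as a single staircase of logistic steps sharing
plateau levels. Per-span fits absorb neighbouring transition tails and can
bias `T0` by up to ~0.5 °C on a noiseless three-transition curve; the joint
fit removes this. Intersection temperatures, however, are computed from the
*independent span fits*: refined sigmoids share exact asymptote levels and
are tangent rather than crossing, whereas independently fitted neighbours
carry the small level mismatches that make the intersections exist — which
is also how per-region fits in standard analysis software behave.

**Intersections and onset.** `T_I` is the root of `s_i(T) − s_{i+1}(T)`,
located by scanning for sign changes on a fine grid (endpoint bracketing
misses paired crossings when levels nearly match) and refining with
`uniroot`; among multiple crossings the one nearest the midpoint between
the two `T0` is taken. `T_onset` defaults to the thermal-analysis tangent
construction — the intersection of the low-temperature plateau line with
the tangent to the first sigmoid at its midpoint, which for a flat plateau
at the lower asymptote reduces to `T0 − 2·dT`; a threshold definition
(first crossing of 5% of the first sigmoid's amplitude, linearly
interpolated) is selectable. Both are reporting conventions, labelled as
such in every report.

## Per-region thermodynamics

Each sigmoidal region is treated as a separate two-state equilibrium. The
region-local fraction `f_i = (y − y0_i)/(ymax_i − y0_i)` needs reference
signals for the initial and final conformations of that region;
`melt_control(region_refs = )` offers three choices:

* `"model"` (default): boundary reference lines implied by a **van't Hoff
  staircase** refit of the whole curve — steps logistic in 1/T (the true
  shape of a two-state equilibrium occupancy; a Boltzmann staircase,
  symmetric in T, mis-places the plateau levels of sharp transitions by a
  few percent, which `ln K` amplifies into ΔS errors of 4–6%) plus a
  linear drift term absorbing the residual baseline tilt that
  constant-referenced curves retain. A level-proportional modulation term
  was trialled and rejected: it halves the residual bias but nearly
  doubles the reference variance. Enthalpies are carried in units of
  10⁵ J/mol inside the optimiser so all parameters share a common scale.
* `"plateau"`: lines fitted to the bounding plateaus (asymptote constants
  where a bounding plateau is missing or too short). Extrapolating a
  tail-contaminated plateau line across a region amplifies its slope error.
* `"sigmoid"`: the sigmoid's own `A1/A2` as constants.

Points with `f_i` outside `(0.02, 0.98)` are excluded before `K = f/(1−f)`
(`ln K` diverges; the margin is configurable and barely interacts with the
transition window below). `ΔG = −R·T(K)·ln K` uses `R = 8.314` J/(mol K)
and Kelvin inside the logarithm, reported in kJ/mol.

The transition-region line `ΔG = ΔH − T·ΔS` is fitted **against temperature
on the Celsius axis**. This convention is deliberate: the reported
per-region values then satisfy `ΔH = T_m(°C)·ΔS` identically (the root of
the fitted line is `T_m`), which is the internal consistency the printed
formulation tables exhibit (e.g. 120/1.56 = 76.9 ≈ 77.0 °C), and the totals
`ΔG_total = ΔH_total − T_ref·ΔS_total` reproduce the printed totals only on
this axis. The physically conventional van't Hoff enthalpy
`ΔH_vH = T_m(K)·ΔS` is computed from the same regression and always
reported alongside. The `|ΔG| < 5` kJ/mol window is anchored on the fitted
sigmoid — membership via `|T − T0| ≤ window/ΔS₀` with
`ΔS₀ = R·T_m(K)/dT` — rather than on each point's own noisy ΔG, so window
membership is deterministic and not co-selected with the noise; only the
contiguous run around the ΔG zero crossing is used, because a neighbouring
transition can bring `|ΔG|` back under the window far from this region's
midpoint. The fit itself is unweighted ordinary least squares; standard
errors come from its covariance, totals combine in quadrature.

`ΔG_total` is evaluated at `T_ref` = the last intersection temperature
(falling back to the last `T_m` for single-region data). This reference
rule reproduces the printed total free energies and is flagged in every
report as a convention.

## The synthetic generator

`melt_spec()` builds melts as 1–3 sequential van't Hoff transitions
(`p_i = K_i/(1+K_i)`, `K_i = exp(−(ΔH_vH/R)(1/T_K − 1/T_m,K))`) riding on
linear baselines, sampled on the instrument grid 25–97 °C in 1 °C steps,
with homoscedastic Gaussian noise. The generative ΔS under the
Celsius-axis convention is `ΔH_vH/T_m(K)` by construction. Presets:

* `"f1il-like"` — the hardest case: midpoints 52.4/67.5/86.8 °C with
  entropies 910/2200/960 J K⁻¹ mol⁻¹ (rise, rise, fall; fraction levels
  0 → 0.45 → 1 → 0.4, chosen once to match the published rise–rise–fall
  shape);
* `"f1-like"` — one transition, 77.0 °C, 1560 J K⁻¹ mol⁻¹;
* `"water-like"` — 75.5 and 91.83 °C, 1230/3090 J K⁻¹ mol⁻¹, second
  falling (Gaussian overall shape).

Default noise is 1% of the mean baseline separation. Baselines default to
MRE-like values (negative 218 nm band, −3000·…·−6500 deg cm² dmol⁻¹ with
small positive slopes). `generate_full_spectra()` embeds the melt in
Gaussian bands (negative at 218 nm, positive beta-turn band at 202 nm)
normalised so the 218 nm column reproduces the single-wavelength signal
exactly at zero noise.

What the generator does **not** emulate: heteroscedastic or correlated
instrument noise, HT-voltage artefacts, absorbance flattening, drifting
baselines within a phase, non-two-state (kinetically irreversible)
transitions, or heat-capacity curvature of ΔG. Passing recovery tests
therefore demonstrate estimator correctness under the stated model, not
robustness to every instrument pathology.

## What recovery can and cannot achieve

With three transitions, 1 °C sampling and 1%-of-span noise, the reported
recovery rates (see `scripts/acceptance.R`) are ~99% for all `T_m` within
0.5 °C and 100% for the `T_I` ordering, but only ~66% for all three ΔS
within 10%. This is not an implementation artefact: the sharp middle
region (ΔS ≈ 2200 J K⁻¹ mol⁻¹) restricts the `|ΔG| < 5` kJ/mol window to
±2.3 °C — about five grid points — and an oracle given the *exact*
reference levels and the prescribed unweighted regression still only
reaches ~86% on the same replicates. The corresponding printed table value
carries a ±23% uncertainty, consistent with this floor. The package
reports per-region standard errors precisely so that this variance is
visible to users.

## BLI kinetics

`simulate_1to1()` uses the closed pseudo-first-order forms
(`R = Req(1 − e^{−(kon·C+koff)t})` in association, exponential decay in
dissociation; analyte depletion neglected). The 1:2 model comes in two
forms: `parallel_sites` (default; the sum of two independent 1:1
components, matching a fit parameterised by independent
`kon/koff/Rmax` pairs for the first and second binding phases) and
`sequential_bivalent` (mechanistic avidity `A + L ⇌ AL`, `AL + L ⇌ AL2`
integrated as ODEs on site fractions with free sites `1 − AL − 2·AL2`;
`kon2` is an effective rate in s⁻¹ multiplying the free-site *fraction*,
since the molarity of immobilised sites on a sensor tip is undefined;
statistical factors for bivalency are deliberately omitted).
`bli_fit()` does Levenberg–Marquardt least squares over log-scaled
parameters with deterministic linearised initialisation (koff from the
log-linear dissociation tail, kon from `kobs = kon·C + koff`) and, for the
biphasic model, a small deterministic multi-start over rate-splitting
ratios (biphasic traces are prone to local minima from a single start).
Fits whose parameters run to the working-range limits are flagged
`converged = FALSE`. RMSE is reported per model so a 1:1 vs 1:2 comparison
can mirror experimental model rejection; `fit_bli_file()` flags likely
over-parameterisation when 1:2 improves RMSE by under 5%.

One identifiability note: with `koff ≈ 5·10⁻⁴ s⁻¹` a 120 s dissociation
observes only ~6% decay and `koff` then carries ~12% sampling error
regardless of the fitting method; the recovery properties therefore
simulate a 300 s dissociation — assay length matched to the kinetics being
measured. Simulator defaults keep the published protocol shape (1 min
baseline, 2 min association).

## Problem sizes and reproducibility

The test-suite and acceptance runs use 73-point melt grids, 200 melt
replicates, 30–50 sensorgram replicates of ~1500–2300 points, and tight
deterministic seeds throughout; everything (fixtures included) is generated
in code at run time. Reports record the package version, input digest,
seed and full configuration, and re-running with the same inputs is
bit-reproducible.

```{r example}
library(mabtherm)
spec <- melt_preset("f1il-like", seed = 42)
fit <- melt_fit(generate_cd_signal(spec))
summary(fit)
plot(fit)
```

## Known limitations

* The number of transitions is whatever plateau detection implies; there is
  no information-criterion comparison across `r`.
* `T_onset` and the `ΔG_total` reference temperature are reporting
  conventions (flagged in reports), not instrument observables.
* No heat-capacity (ΔCp) term: ΔG is linear in T within each window.
* The 1:2 sequential-bivalent form is a minimal site-fraction model; no
  mass-transport limitation, no global multi-concentration fits.
* Full secondary-structure deconvolution of CD spectra is out of scope;
  only the 218 nm band is analysed.
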