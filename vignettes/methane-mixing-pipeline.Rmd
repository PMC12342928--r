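---
title: "Methods: methane cycling diagnostics in a water-mass mixing region"
author: "methanemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methane cycling diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanemix)
```

This vignette documents the models behind each stage of the pipeline, the
choices made where the method left room, and what the synthetic tests do —
and do not — establish about real data.

## 1. Optimum multiparameter (OMP) water-mass analysis

### Model

A water sample is modelled as a non-negative mixture of `n` endmember water
masses, each defined by a fixed sextuple of quasi-conservative properties:
potential temperature, salinity, dissolved oxygen, phosphate, nitrate and
silicate. For each property `P` and sample observation `P_obs`,

    x_1 P_1 + ... + x_n P_n = P_obs + R_P,      x_1 + ... + x_n = 1 + R_M,

and the mixing fractions `x_i >= 0` minimize the weighted sum of squared
residuals. Oxygen and nutrients are not strictly conservative
(remineralization consumes O and releases P, N, Si); standard OMP practice
treats them as quasi-conservative over the upper water column, and the
residuals `R_P` absorb — and diagnose — the non-conservative part.

### Numerical choices

* **Scaling.** The six properties carry incommensurate units, so "optimum"
  is only defined after scaling. Each property row is divided by the
  across-endmember standard deviation of that property, using the
  *population* convention (divisor `n`), then multiplied by its property
  weight. The convention matters (it fixes what the scaled coefficients
  are) and is therefore stated and tested. Properties with zero spread
  across endmembers carry no mixing information and are excluded with a
  warning rather than dividing by zero.
* **Constraints.** Non-negativity is enforced by a Lawson–Hanson
  non-negative least-squares solve of the stacked system
  (`pracma::lsqnonneg`). Mass conservation enters as a row of ones scaled
  by `mass_weight` (default 100× the property weights): a heavily weighted
  *soft* constraint. This keeps `Σx` within ~1e-4 of 1 in practice while
  still defining a mass residual `R_M`, and it makes the solver a plain
  NNLS rather than a constrained QP. Raising `mass_weight` can only shrink
  `|R_M|` (tested as a monotonicity property).
* **Endmember count.** Two to seven endmembers are accepted: with six
  property equations plus the mass row, more than seven unknowns would be
  underdetermined. Region-typical uses have two (Kuroshio/Oyashio surface
  mixing) or three (adding North Pacific Intermediate Water at depth).
* **Flagging, never deletion.** Solutions whose native-unit residuals
  exceed a configurable threshold (a sensible default is twice the
  measurement noise sd) are flagged `low_confidence`; per-sample failures
  inside `omp_section()` become flagged rows, never an aborted section.
* **Ties.** Dominant-mass classification is argmax with ties broken by
  endmember order and flagged.

The default endmember property values shipped in `default_endmembers()`
are explicit placeholders: the salinity extremes match the observed
transect range (33.2–35.1) and the nutrient/oxygen contrasts are
field-plausible, but any real analysis must supply endmembers read off its
own T–S diagrams (`endmember_set()` or an endmember table file).

### Verification

The solver is checked against an independent brute-force oracle: a dense
grid over the probability simplex (step 0.01) evaluating the same weighted
objective by enumeration. On 200 random noisy 3-endmember samples the NNLS
objective is never worse than the best grid candidate; noiseless mixtures
are recovered to 1e-9. On a synthetic 20-station × 8-depth section with
measurement-scale noise (T 0.005 °C, S 0.003, O 1 µmol l⁻¹, P 0.02, N 0.1,
Si 0.5 µmol l⁻¹ — typical CTD/autoanalyzer precision), the mean absolute
fraction error is ~0.003; the acceptance tolerance is set at 0.01, about
three times the simulated error, fixed from that calibration.

## 2. Tracer kinetics

First-order oxidation: the turnover fraction is the product activity over
the total activity, and `k = (DPM_product / DPM_total) / t`, with
`MOx = k · [CH₄]_in situ`. Choices:

* **Control correction on the fraction scale.** The killed control's
  turnover fraction is subtracted from each live replicate *before*
  division by `t`; fractions are what the counter measures and `t` is
  shared. The correction is switchable (`correct_control`), since assays
  differ in whether the control is used quantitatively; it is on by
  default. Negative corrected fractions clip to zero with a flag — a
  first-order rate constant is physically non-negative.
* **Counting noise** is modelled as Gaussian with SD = √DPM (the Poisson
  approximation for scintillation counting). At the assay's activity
  (≥ 10⁵ DPM total, 48-h incubations), simulated recovery across
  k ∈ [0.001, 0.05] d⁻¹ shows a median relative bias well under 1%.
* Incubation time defaults to 2 days (48 h) but is a per-record field.

## 3. Gas exchange

The chain is: water-vapor pressure `f(T_eq, S)` → equilibrator pCO₂ →
temperature (warming) correction to in situ pCO₂ → Schmidt numbers →
transfer velocity → fluxes and saturation.

All empirical coefficients live in one documented table (`gas_coefs`):
the quartic Schmidt-number fits for CH₄ and CO₂ in seawater and the 0.251
quadratic transfer-velocity coefficient from the standard wind-speed
parameterization, the seawater CH₄ equilibrium solubility fit, and the CO₂
solubility (K_H) fit. Isolating them makes the parameterizations
swappable without code changes and keeps their provenance auditable.
Fixed-point checks: Sc(CO₂, 20 °C) = 668; f(298.15 K, S = 35) =
0.0307 atm; CH₄ equilibrium at 25 °C, S 35, 1900 ppb ≈ 2.1 nmol l⁻¹;
K_H(20 °C, 35) ≈ 0.033 mol l⁻¹ atm⁻¹.

* **Units.** Fluxes are computed natively in µmol m⁻² h⁻¹
  (cm h⁻¹ × nmol l⁻¹ → ×0.01) and converted for reporting
  (×8.766 to mmol m⁻² y⁻¹, using the 8766-h mean year); conversions are
  exact and tested as round trips. Positive flux is sea→air; a negative
  CO₂ flux is ocean uptake.
* **Range guards.** The vapor-pressure fit refuses temperatures outside
  270–320 K (catching Celsius/Kelvin mix-ups), the Schmidt fits refuse
  SST outside −2–40 °C, and the warming correction refuses
  |SST − T_eq| ≥ 10 °C — silent extrapolation of empirical fits is the
  main failure mode these guards close.
* Wind speed is used instantaneously per record; no averaging scheme is
  applied.
* Atmospheric CH₄ may be supplied as a dry mole fraction (converted
  through the solubility fit) — the equilibrium-concentration path — and
  atmospheric pCO₂ directly in µatm.

## 4. Dilution and driver attribution

If methane mixed conservatively between two endmember waters, its
concentration would be linear in salinity between the endmember (S, CH₄)
pairs. Residuals from that line are the diagnostic: negative = net
consumption (e.g. oxidation), positive = net production. Default
endmembers are the observations at the salinity extremes of the input —
the transect-extreme framing; they are configurable. Predictions outside
the endmember salinity range are flagged as extrapolation.

Per-predictor "shares of methane variability" from the multiple
regression are computed by averaging sequential sum-of-squares
contributions over all predictor orderings (the LMG decomposition,
implemented via the all-subsets formula). This is the standard
order-independent attribution; shares are reported as percent of total
response variance, so they sum to R² × 100 — exactly 100% of the explained
part — and are permutation-symmetric (tested). Collinearity beyond a
condition-number threshold flags the shares but does not suppress them.
p-values are reported without multiple-testing correction.

## 5. Incubation analysis

Net accumulation is the treatment's concentration change minus the
control's, replicate-averaged with propagated sd; it is invariant to
adding a constant to all concentrations. The control correction is
time-matched subtraction of control means. Lag detection uses a
sustained-exceedance rule: the earliest sampling time at which the
control-corrected mean exceeds `threshold_sd` × the pooled replicate sd
*and stays above it* to the end of the series. At the sparse time
resolution of shipboard amendment experiments (samples every ~2 days),
breakpoint regression is unstable; the sustained rule is robust, at the
cost that a lag ending between sampling times is reported at the next
sampling time. Raising the threshold can only lengthen the detected lag
(tested). With triplicates and a 3-sd threshold, pure-noise series trigger
falsely in well under 5% of simulations.

## 6. Budget

Depth-integrated MOx uses the trapezoidal rule (standard for bottle
profiles), with the profile extended to the surface at the shallowest
value (flagged) and interpolated at the integration depth when it falls
between samples. The default integration depth is 300 m — the upper water
column — and is configurable. Downward extrapolation past the deepest
sample is refused. `nmol l⁻¹ d⁻¹` equals `µmol m⁻³ d⁻¹`, so the integral
is in µmol m⁻² d⁻¹ directly.

The microbial share of methane removal is
`100·∫MOx/(∫MOx + F_CH₄)`, the two-term loss budget. When the air–sea
flux is negative (the sea is momentarily a CH₄ sink) it is not a loss from
the water column: the flux is floored at 0 for the ratio and the record
flagged. The fraction is scale-invariant in its two arguments (tested).

## 7. The synthetic-data generator

The generator's defaults encode the study conditions of a
Kuroshio–Oyashio-type frontal transect: surface salinity spanning
33.2–35.1 and SST 16.8–30.2 °C between 40° N and 35° N; surface pCO₂
rising southward from 338 to 360 µatm against dissolved CH₄ falling from
6.11 to 5.15 nmol l⁻¹ (the conservative-dilution signature); wind
7.31 ± 1.38 m s⁻¹; triplicate tracer incubations plus a killed control at
10⁵ DPM total activity and 2-day incubations; rate constants within
0.001–0.05 d⁻¹; 300-m budgets. Property noise defaults are instrument-
scale (see §1). These values were fixed once, from the conditions above,
and are configuration rather than constants.

Design details: measurement noise is independent Gaussian per property;
counting noise is Gaussian with SD = √DPM; a single master seed fans out
to fixed per-stage substreams so each generator is independently
reproducible; fraction fields must lie on the simplex and are rejected
with the offending station/depth named. The default mixing profile places
the warm mass in the south, the cold mass in the north, and (in the
three-endmember scenario) intermediate water growing with depth. The dry
xCO₂ of the underway generator is back-computed from the target in situ
pCO₂ through the same vapor-pressure/warming chain, so the processing
chain recovers the intended values exactly when noise is off — a
round-trip identity used by the tests.

### What the synthetic tests do and do not show

They establish that the estimators are implemented correctly: exact
recovery in noiseless limits, unbiased recovery at realistic noise,
correct propagation of known anomalies, and determinism under a fixed
seed. They do not establish that real frontal-zone data satisfy the
models' assumptions — endmembers are not truly fixed points, oxygen and
nutrients are only quasi-conservative, methane anomalies mix laterally,
and amendment incubations are not in situ conditions. Residual
diagnostics (OMP residuals, dilution residuals, regression diagnostics)
are the tools the package provides for judging that on real data.

### Problem sizes

The shipped tests and the acceptance script use 20 stations × 8 depths for
OMP recovery, 200 grid-oracle samples, 10³ simulated tracer incubations,
200-record underway transects, 10⁴-replicate noise-moment checks, and
20-station budget regions — sizes at which Monte-Carlo error is well below
the tested tolerances while the full suite runs in seconds.

## Known limitations

* No time-dependent OMP, nonlinear mixing, or conversion from in situ to
  potential temperature (inputs are assumed converted).
* The budget has exactly two loss terms: no lateral advection or vertical
  diffusion.
* No bubble-mediated flux, wind reanalysis ingestion, or instrument-side
  corrections.
* The dilution model is strictly two-endmember; in a three-mass regime its
  residuals conflate the third mass with biogeochemistry.
* Default endmember definitions are placeholders, not regional truth.
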