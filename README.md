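# methanemix

Diagnostics for marine methane cycling in water-mass mixing regions.

Frontal zones where distinct ocean currents meet — the archetype being the
Kuroshio–Oyashio Extension in the Northwest Pacific, where warm, saline,
oligotrophic subtropical water mixes with cold, fresh, nutrient-rich
subarctic water — reshuffle dissolved methane, the microbes that produce
and consume it, and the physics that vents it to the atmosphere. This
package implements the computational chain needed to take station profiles,
underway surface records and incubation experiments from such a region and
turn them into a quantitative picture of the methane cycle:

1. **Water-mass analysis (OMP).** Each sample is decomposed into fractional
   contributions `x_i ≥ 0` of predefined endmember water masses by solving
   the property-conservation system over six hydrographic tracers
   (potential temperature, salinity, dissolved oxygen, phosphate, nitrate,
   silicate) plus mass conservation:

   `Σ_i x_i P_i = P_obs + R_P` for each property `P`, and `Σ_i x_i = 1 + R_M`,

   by weighted non-negative least squares (properties standardized across
   endmembers; the mass row is a heavily weighted soft constraint).

2. **Methane-oxidation kinetics.** Tritiated-methane incubations give the
   first-order rate constant `k = DPM(³H-H₂O) / DPM(³H-H₂O + ³H-CH₄) / t`
   and the oxidation rate `MOx = k · [CH₄]_in situ`, with killed-control
   correction on the turnover-fraction scale and triplicate statistics.

3. **Gas exchange.** Equilibrator xCO₂ is converted to in situ pCO₂
   (water-vapor correction `pCO₂(eq) = xCO₂/(1−xH₂O) · (P_eq − f)` with
   `ln f = 24.4543 − 6745.09/T_eq − 4.8489 ln(T_eq/100) − 0.000544 S`, then
   warming correction `exp[0.0423(SST − T_eq)]`). Air–sea fluxes use the
   quadratic wind-speed transfer velocity `k = 0.251 u² (Sc/660)^−1/2`,
   gas-specific Schmidt numbers, and seawater solubility fits:
   `F_CH₄ = k_CH₄([CH₄]_water − [CH₄]_eq)` and `F_CO₂ = k_CO₂ K_H ΔpCO₂`.

4. **Dilution analysis.** A conservative two-endmember CH₄–salinity mixing
   line; residuals below the line diagnose net consumption, above it net
   production. A driver-attribution regression (LMG averaging over
   orderings) splits explained methane variability among temperature,
   salinity, oxygen saturation, etc.

5. **Incubation analysis.** Net methane accumulation, production rates and
   onset lags from DMSP/methylphosphonate amendment time courses.

6. **Budget.** Depth-integrated MOx (trapezoidal, default upper 300 m)
   combined with the sea–air flux gives the microbial share of total
   methane removal: `100 · ∫MOx dz / (∫MOx dz + F_CH₄)`.

A synthetic-data generator (`scenario_config()`, `generate_section()`,
`generate_tracer_incubations()`, `generate_underway()`,
`generate_amendment_timeseries()`) produces every pipeline input with known
ground truth, so the whole chain is testable end to end without any cruise
data.

## Worked example

```r
library(methanemix)

# 1. water-mass fractions of a mid-front sample
em <- default_endmembers(2)          # Kuroshio / Oyashio placeholders
sample <- data.frame(station = "P07", depth_m = 50,
                     T = 12.1, S = 34.18, O = 262, P = 1.05, N = 11.4,
                     Si = 24.1)
solve_omp(sample, em)
#> OMP solution (station P07, 50 m)
#> Kuroshio  Oyashio
#>   0.5085   0.4915
#> sum(x) = 1.00003  objective = 0.002447

# 2. methane oxidation from a tracer incubation
k <- rate_constant(dpm_product = 120, dpm_total = 2400, t = 2)
mox_rate(k, ch4_in_situ = 3.77)
#> k = 0.025 d-1;  MOx = 0.09425 nmol l-1 d-1

# 3. air-sea CH4 flux at 18 C, salinity 34.2, 7.31 m/s wind
kg  <- gas_transfer_velocity(7.31, schmidt_number(18, "CH4"))
ceq <- ch4_equilibrium_concentration(18, 34.2, 1900)
ch4_flux(kg, ch4_water = 3.1, ch4_equilibrium = ceq)
#> k_gas = 12.52 cm/h; CH4_eq = 2.416 nmol/l; F_CH4 = 0.75 mmol m-2 y-1

# 4. microbial share of total methane removal
mox_fraction(0.7, 0.9)$fraction_pct
#> 43.75
```

The sample at 50 m sits almost exactly on the 50/50 mixing line of the two
endmembers; the tracer vial turns over 5% of its methane pool in two days
(`k = 0.025 d⁻¹`), oxidizing 0.094 nmol l⁻¹ d⁻¹ at the in situ
concentration; the surface water is oversaturated and vents
0.75 mmol CH₄ m⁻² y⁻¹; and where depth-integrated oxidation (0.7) and
flux (0.9, same units) coexist, microbes account for 43.75% of total
methane removal.

A complete demonstration, from synthetic inputs to budget tables:

```r
cfg_file <- write_demo_inputs("demo", scenario_config(seed = 1))
run_pipeline(cfg_file)   # writes omp/mox/flux/dilution/budget tables
```

or from a shell via the bundled CLI:

```sh
Rscript inst/cli/methanemix.R simulate --out demo --seed 1
Rscript inst/cli/methanemix.R pipeline --config demo/pipeline.cfg
```

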