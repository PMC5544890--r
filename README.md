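# macroflux

Static-chamber methane fluxes from stands of emergent aquatic
macrophytes — estimation, screening, and temporal analysis.

Rooted emergent plants (reeds, sedges) carry CH₄ from anoxic lake
sediments directly to the atmosphere through their aerenchyma, bypassing
the oxidation zone; in vegetated littoral zones this pathway dwarfs the
diffusive flux across the water surface. The standard field measurement
is a closed (static) chamber over a plant stand, with a greenhouse-gas
analyser logging headspace CH₄ and CO₂ every 20 s for 5 min. `macroflux`
turns those logs into fluxes and into the statistics a seasonal, diel
campaign needs:

* **Windowed slope selection** — discard the first minute (mixing), fit
  every 2-min ordinary-least-squares window offset by 20 s (seven under
  the default protocol), keep the window with the highest r², and
  convert its slope (ppm d⁻¹) to an areal flux by the ideal gas law:

  F = slope/10⁶ · P·V/(R·T) · 1000/A  [mmol m⁻² d⁻¹],

  with R = 0.082056 L atm K⁻¹ mol⁻¹, V the chamber volume (197.4 L
  default), A its base area (0.1849 m²).
* **Ebullition screening** — bubble events show up as a sudden
  concentration step plus degraded whole-record linearity; flagged
  enclosures are excluded from statistics.
* **Diffusive flux** — F = k·(C_w − C_eq), with C_eq from Henry's law
  under a van 't Hoff temperature dependence.
* **Diel agreement** — 10 time classes per 24-h series and a two-way
  absolute-agreement intra-class correlation across days.
* **Daily-mean regressions** — daily flux vs temperature, wind, light,
  NEE, with t-based 95% CIs.
* **Gamma GLZ model averaging** — all 2304 models nested in the full
  log-link Gamma GLM (8 free terms × date and time polynomials), AIC
  ranking, Akaike-weight model averaging with unconditional SEs and
  relative importance, after standardizing continuous predictors to
  mean 0, SD 0.5 and screening collinear drivers.
* **Synthetic campaigns** — a generator that emulates the two-lake,
  two-species seasonal design with known ground truth, so the whole
  chain is testable end to end (zero-noise data round-trip exactly).

See `vignette("chamber-methane-pipeline")` for the methods in detail.

## A worked example

```r
library(macroflux)

study <- simulate_chamber_study(sim_config(seed = 42))
study
#> Synthetic chamber study
#>   372 enclosures in 25 daily series (2 lakes, 2 species)
#>   5952 gas-log records; 1 ebullition events injected; seed 42

# one enclosure, by hand
g   <- study$gas_log[study$gas_log$enclosure_id == "E0100", ]
enc <- study$enclosures[study$enclosures$enclosure_id == "E0100", ]
chamber_flux(g$t_s, g$ch4_ppm, g$co2_ppm, temp_c = enc$air_temp_c,
             pressure_atm = enc$pressure_atm,
             biomass_gdw_m2 = enc$biomass_gdw_m2, id = "E0100")
#> Chamber flux estimate (E0100)
#>   CH4 flux: 4.706 mmol m-2 d-1 (3.145 mg CH4 m-2 h-1)
#>   CO2 flux (NEE): 183.1 mmol m-2 d-1
#>   window: start 100 s, slope 105.0 ppm d-1, r2 0.9185 (of 7)
#>   per biomass: 0.2088 mmol gDW-1 d-1 (22.5 g DW m-2)
#>   ebullition flag: FALSE

# the whole chain
run_pipeline(study)
#> Chamber flux pipeline result
#>   enclosures: 372 read, 2 excluded as ebullition, 322 modeled
#>   diel ICC (single): 0.159 (P = 1.53e-16)
#>   strongest daily-mean regression: mean_air_temp_c (slope 0.633, P = 0.0432, adj R2 = 0.13)
#>   collinearity screen dropped: chamber_temp_c, humidity
#>   model averaging: 2304 candidates over 322 observations
```

Reading the output: the chosen regression window started 100 s into the
enclosure with r² = 0.92; the 4.7 mmol m⁻² d⁻¹ CH₄ flux (equivalently
3.1 mg CH₄ m⁻² h⁻¹) sits close to the injected ground truth
(3.6 mmol m⁻² d⁻¹ — the gap is analyser noise plus best-window
selection at a weak slope). Down the chain, hourly days are thinned to
12 measurements, chamber temperature and humidity fall to the
collinearity screen (|r| > 0.7 with air temperature), and the averaged
Gamma GLZ table (`run_pipeline(study)$averaged`) reports, as built into
the generator, a strong positive air-temperature effect and a negative
coefficient for the reference-vs-other lake indicator, both with
relative importance 1, while the species term hugs zero.

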