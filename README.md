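# leaftherm

Leaf energy balance and thermoregulation analysis for forest-canopy
microclimate studies.

Leaves in a canopy are not at air temperature: under sun they can run many
degrees hotter, and their excess temperature ΔT = T_L − T_A depends on
radiation load, wind, leaf size and stomatal behaviour. `leaftherm`
implements the full analysis chain used to study these patterns from
tower-based microclimate profiles and leaf-mounted thermocouples:

* **Microclimate derivation** — Tetens saturation vapour pressure
  e_sat = a·exp(bT/(T+c)), vapour pressure deficit D = e_sat(1−h),
  per-height humidity gap-filling from the h–T_A coupling, wind
  interpolation across anemometer heights.
* **Steady-state leaf energy balance** — the isothermal net-radiation form

  ΔT_e = r_bHR · γ · (r_bW + r_lW) · R_ni / (ρ_a c_pa [γ(r_bW + r_lW) + s·r_bHR])
  − r_bHR · D / [γ(r_bW + r_lW) + s·r_bHR]

  a radiative warming term minus an evaporative cooling term, with the
  boundary-layer conductance g_bH = a(U/W)^b coupling leaf width W and wind
  speed U.
* **Boundary-layer recalibration** — closed-form inversion of the balance
  for the boundary-layer resistance to water r_bW from observed ΔT, then
  nonlinear least squares to re-estimate the coefficient `a` per species
  (one- and two-parameter models, wind-binned summaries with Tukey-fence
  outlier exclusion and a PAR ≥ 200 µmol m⁻² s⁻¹ gate).
* **Stomatal response** — species-level linear g_s–D models fitted as
  mixed-effects models with a random intercept per leaf (leaf-specific
  intercept, species-specific slope), plus the thermal time constant
  τ = φ·LMA·[c_pw/LDMC + c_pd − c_pw]/H.
* **Window-regression data selection** — per-20-minute OLS of predicted on
  observed ΔT; windows are kept when the slope is 1 ± 0.3 and the intercept
  within ±2 °C, certifying that tower-measured PAR represented the leaf
  surface.
* **Species contrasts** under matched microclimate bins (mixed models with
  leaf random intercepts, Nakagawa–Schielzeth pseudo-R²) and
  **trait-substitution counterfactuals** (re-predicting ΔT_e with a donor
  species' leaf width and/or stomatal strategy).
* **A seeded synthetic canopy generator** producing microclimate profiles,
  spot g_s campaigns and observed ΔT series with the statistical structure
  the analysis assumes, so every stage is testable end to end without field
  data.

## Worked example

Predict the temperature excess of a sunlit leaf (PAR 1500 µmol m⁻² s⁻¹,
20 °C, 70 % humidity, wind 1 m s⁻¹, width 10 cm, g_s 300 mmol m⁻² s⁻¹ at
90 kPa):

```r
library(leaftherm)
eb <- leaf_air_temperature_difference(
  PAR = 1500, T_A = 20, h = 0.7, U = 1, W = 0.1,
  g_s = gs_to_velocity(300, T_A = 20, P_atm = 90))
round(eb[, 1:5], 3)
#>   delta_T_e  T_Le    R_ni radiative_term evaporative_term
#> 1      4.15 24.15 328.228          5.579            1.429
```

The leaf runs 4.15 °C above air temperature: absorbed radiation would warm
it by 5.58 °C, transpiration claws back 1.43 °C.

Fit the stomatal response on a synthetic spot campaign (three species,
10 leaves each, 20 daytime spots per leaf):

```r
scn <- synthetic_scenario(seed = 42, n_days = 2)
fit <- fit_gs_D_model(gen_stomatal_observations(scn))
fit
#> Stomatal g_s-D response (lme fit), per species:
#>   sp_A: g_s = 335.8 (+/-11.8) -70.4 (+/-17.6) D
#>   sp_B: g_s = 408.5 (+/-11.7) -175.3 (+/-19.3) D
#>   sp_C: g_s = 178.0 (+/-12.0) -192.1 (+/-23.8) D
#>   30 leaves; floor g_min = 5 mmol m-2 s-1
```

Each recovered intercept/slope pair sits within two standard errors of the
generator's species truths (325.1/−68.8, 401.6/−189.8, 185.4/−212.7). The
full pipeline — simulate, derive, fit, invert, calibrate, select windows,
contrast species, swap traits — runs with:

```r
summary <- run_pipeline(pipeline_config(out_dir = "run", seed = 1))
```

writing stage CSVs, `summary.json` and a log under `run/`.

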