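---
title: "Methods: leaf energy balance, calibration, and the synthetic canopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf energy balance, calibration, and the synthetic canopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaftherm)
```

# The model

`leaftherm` treats a leaf as a steady-state energy balance: absorbed net
radiation is dissipated by sensible heat exchange, longwave re-emission and
transpiration. Linearising the saturation curve about air temperature gives
the leaf-to-air temperature difference as the difference of two terms,

$$\Delta T_e \;=\;
\frac{r_{bHR}\,\gamma\,(r_{bW}+r_{lW})\,R_{ni}}
     {\rho_a c_{pa}\,[\gamma (r_{bW}+r_{lW}) + s\, r_{bHR}]}
\;-\;
\frac{r_{bHR}\, D}
     {\gamma (r_{bW}+r_{lW}) + s\, r_{bHR}},$$

a radiative warming term and an evaporative cooling term. Here $r_{bHR}$ is
the parallel boundary-layer resistance to heat and radiation (s/m),
$r_{bW}$ and $r_{lW}$ the boundary-layer and leaf (stomatal) resistances to
water vapour, $\gamma$ the psychrometric constant (Pa/K), $s$ the slope of
the saturation vapour-pressure curve at air temperature (Pa/K), $R_{ni}$
the net isotropic radiation (W/m²) and $D$ the vapour pressure deficit (Pa
inside the equation; kPa at the user interface). The assumptions are the
standard ones: no heat storage in the lamina (steady state), sky
temperature equal to air temperature, and well-mixed leaf surface
conditions. An exact identity follows from the algebra — sensible plus
latent flux reconstructed from the returned resistances equals $R_{ni}$ —
and the test suite asserts it to numerical precision; it is a useful guard
against sign and unit errors.

## Resistance network and closures

The convective conductance follows the flat-plate forced-convection law
$g_{bH} = a\,(U/W)^b$ with defaults $a = 0.0105$ m s$^{-1/2}$, $b = 0.5$;
leaf width $W$ in metres, wind speed $U$ in m/s floored at 0.05 m/s so that
resistances stay bounded in near-still air (the calibration stage, not the
floor, is the answer to the law's known overprediction of resistance at low
wind). Three closures complete the network and are deliberately plain,
configurable constants:

* $g_{bW} = 1.08\, g_{bH}$ — the water/heat diffusivity-ratio correction;
* $r_{bHR} = 1/(g_{bH} + g_{bR})$ — convective and radiative paths in
  parallel, with $g_{bR} = 4 \epsilon_{leaf} \sigma T_K^3/(\rho_a c_{pa})$
  the linearised longwave-exchange conductance;
* $R_{ni} = \alpha_{SW}\,(PAR/q)\,/f_{PAR} + (\epsilon_{sky} -
  \epsilon_{leaf})\,\sigma T_K^4$ with shortwave absorptance
  $\alpha_{SW} = 0.5$, quanta-to-energy conversion $q = 4.57$ µmol/J and
  PAR fraction $f_{PAR} = 0.5$; with the default equal emissivities (0.97)
  the longwave term vanishes exactly.

The power law is treated as the whole-leaf conductance on a projected-area
basis with no extra two-sidedness factor: the calibration below absorbs
geometry into the fitted coefficient, which is the point of calibrating
against observed ΔT rather than trusting the textbook constant.

Air density comes from the ideal-gas law at the configured pressure
(default 90 kPa, ≈1000 m elevation) unless overridden;
$\gamma = c_{pa} P/(0.622\,\lambda_v)$, about 60 Pa/K at 90 kPa. Stomatal
conductance measured in porometer units (mmol m⁻² s⁻¹) is converted to
velocity units by $g = g_{mol} R T_K / P$.

## Inverting for the boundary-layer resistance

Solving the balance for $r_{bW}$ given an observed ΔT (with $r_{bHR}$ held
coupled through $g_{bW} = 1.08\,g_{bH}$) turns out to be exactly quadratic
in $r_{bW}$ once the coupling is substituted, so the package solves it in
closed form with the numerically stable quadratic formulation rather than a
root search. The root structure is physically informative:

* radiation-dominated observations (leaf warmer than air) have exactly one
  positive root — the inversion is well posed, and the forward/inverse
  round trip is exact to machine precision;
* evaporation-dominated observations (leaf cooler than air) can admit two
  positive roots: a weakly coupled and a strongly coupled resistance can
  produce the same slight cooling. The observation alone cannot
  distinguish them, so the smaller root is returned with a
  `multiple_roots` flag and such records are excluded from calibration;
* zero forcing ($R_{ni} = 0$, $D = 0$) makes ΔT identically zero whatever
  the resistance; flagged `degenerate`.

This is why the calibration stage — and the round-trip property test — use
bright records (PAR ≥ 200 µmol m⁻² s⁻¹, ΔT > 0): that is the regime where
the radiation signal constrains $r_{bW}$ uniquely.

## Calibration

Per species, inverted resistances are regressed on $U/W$ by nonlinear least
squares, $r_{bW} = 1/(1.08\,a\,(U/W)^b)$, either with $b$ fixed at 0.5
(one-parameter) or free (two-parameter). Choices made where the procedure
was open: the fit is on the resistance scale (with a flag to switch to
conductance), on raw points rather than binned means (binning is kept for
display summaries), with Tukey fences (1.5 × IQR) per 0.1 m/s wind bin as
the outlier rule, and with the 1.08 water/heat factor inside the model so
the fitted `a` remains a heat-conductance coefficient. Asymptotic standard
errors come from the `nls` fit; noise-free data are recovered to well
beyond four significant figures (the `scaleOffset` convergence control
handles the zero-residual case).

# Stomatal response and thermal time constant

Spot conductance campaigns are modelled as
`g_s ~ 0 + species + species:D` with a random intercept per leaf,
REML-estimated via `nlme`: the intercept of the g_s–D line is leaf
specific, the slope species specific. A singular or inestimable fit (e.g.
one leaf) falls back to ordinary least squares with a warning flag.
Predictions are floored at `g_min = 5` mmol m⁻² s⁻¹ because the fitted
lines cross zero at large D, which is unphysical and would break the
energy balance (an infinite stomatal resistance is fine; a negative one is
not).

The thermal time constant uses
$\tau = \phi\,\mathrm{LMA}\,[c_{pw}/\mathrm{LDMC} + (c_{pd} - c_{pw})]/H$
with $H = \rho_a c_{pa}(g_{bH} + g_{bR} + g_s\,s/\gamma)$. The bracketed
grouping is the dimensionally consistent reading of the published form of
this quantity (the typeset equation is ambiguous about the parenthesis);
it makes $\tau$ proportional to LMA (in kg/m²; the trait tables carry
g/m² and are converted), decreasing in LDMC, and decreasing in $H$ —
hence in g_s and wind — which the tests assert as monotonicity and
ratio properties.

# Window-regression data selection

Tower PAR sensors are near, but not on, the leaf; sunflecks and shading
make the recorded PAR occasionally misrepresent the leaf surface. The
filter splits each leaf's daytime series into 20-minute windows aligned to
clock boundaries, regresses predicted on observed ΔT within each window,
and keeps windows with slope in 1 ± 0.3 and intercept within ±2 °C.
Daytime is defined as canopy-top PAR > 5 µmol m⁻² s⁻¹, and a window must
hold at least `n_min` points — half of a full window at the data cadence
(60 at the 10 s field cadence; the generator default of 60 s cadence gives
`n_min = 10`). The regression direction is prediction-on-observation.

Two properties of the filter are worth knowing. First, because the
regressor (observed ΔT) carries measurement noise, the window slope is
attenuated by the noise-to-signal variance ratio; the filter is therefore
meaningful only where the within-window ΔT signal comfortably exceeds the
thermocouple noise. Second, a PAR mismatch on a dim leaf (deep understorey,
twilight) displaces ΔT_e by less than the gates' resolution — such windows
pass whether or not their PAR was corrupted, which is harmless downstream
precisely because PAR does not drive ΔT there. The corruption-rate
calibration in the test suite is therefore evaluated on the fully exposed
overstorey species, where a corrupted window is reliably rejectable and the
selected fraction tracks one minus the corruption rate.

# Species contrasts and counterfactuals

Selected records are subset into half-open microclimate bins
(PAR × T_A × U); the default bins are matched to the climate the default
synthetic scenario produces and are plain configurable lists. Within a bin,
ΔT is contrasted between species by a mixed model with leaf random
intercepts; marginal and conditional pseudo-R² are computed from the
variance decomposition (fixed / fixed+random / +residual) directly off the
fit. Day/night summary statistics use the adjusted Fisher–Pearson sample
skewness, with zero-variance series reported as missing.

Trait-swap counterfactuals re-run the forward balance for a base leaf with
donor-species components substituted — leaf width, g_s–D intercept, g_s–D
slope, or any combination — keeping the base leaf's own microclimate
stream. Swaps act on model parameters only, and composition is exact:
swapping {width} then {intercept} equals swapping both at once (asserted in
the tests). The documented directional effects (wider leaf warms at high
PAR; higher g_s intercept cools; steeper negative slope warms at high D)
are asserted across several random synthetic days.

# The synthetic canopy generator

The generator emulates the statistical structure the analysis assumes, at
the magnitudes of a humid montane forest:

* **PAR**: a half-sine diurnal course peaking at 2000 µmol m⁻² s⁻¹,
  multiplicative cloud flicker in 2-minute blocks (30 % of blocks cloudy,
  transmitting 40–70 %), and Beer-law vertical attenuation
  ($k = 0.25$ m⁻¹) referenced to the top of the leafy canopy at 18 m, so
  exposed top leaves see full sun while the 2 m understorey receives a few
  per cent.
* **Air temperature**: a diurnal cycle whose amplitude is derived
  analytically so the configured daytime canopy-top mean (15.0 °C against
  a 12.4 °C night) is attained in expectation; amplitude damped with depth.
* **Humidity**: linearly and negatively coupled to air temperature
  (h = 2.0 − 0.082 T_A, noise SD 0.012, clipped to [0.05, 1]), putting
  nights near saturation and letting sunny-afternoon D reach ≈ 0.7 kPa.
  The coupling is what makes humidity gap-filling from temperature work,
  and the generated D span is what identifies the g_s–D intercepts.
* **Wind**: lognormal per height, ≈ 0.26 m/s within the canopy and
  1.0 m/s above, linearly interpolated to leaf heights.
* **Species truths**: three species (overstorey mesophyll, overstorey
  platyphyll, understorey notophyll) with g_s–D lines 325.1 − 68.8 D,
  401.6 − 189.8 D and 185.4 − 212.7 D (mmol m⁻² s⁻¹), leaf-offset SD 30,
  spot residual SD 40, boundary-layer coefficients 0.0171, 0.0215 and the
  textbook 0.0105, widths 8, 15 and 5 cm. Ten leaves per species, twenty
  daytime spots per leaf — a deliberately balanced design for the recovery
  experiments.
* **Observed ΔT**: the forward balance under each leaf's true traits and
  g_s(D), plus thermocouple noise (SD 0.02 °C, the resolution of
  individually calibrated two-junction differential thermocouples — and
  small relative to the within-window signal, so the window filter responds
  to radiation mismatch, not measurement noise). In a configurable fraction
  of daytime 20-minute windows the PAR actually driving the leaf is
  rescaled by a factor drawn from {0.3, 2.0} while the recorded PAR is left
  unchanged, emulating sensor/leaf-surface mismatch.

Every generator is a pure function of its scenario (seeded per stage from
the scenario's single seed), so identical scenarios give byte-identical
output.

**What passing tests do and do not show.** The generator's g_s–D process is
exactly the linear mixed model the analysis fits, its ΔT process is exactly
the forward balance being inverted, and its noise is Gaussian and
independent. Recovery and calibration successes on this data certify the
estimation machinery — identifiability, absence of bias, correct error
propagation — not the adequacy of the model for real leaves, where stomata
respond to more than D, radiation errors are not tidy multiplicative
factors, wet leaves evaporate from their surfaces, and sensors drift.

# Problem sizes and numerical choices

The default scenario runs 10 days at 60 s cadence (the field cadence such
loggers use is 10 s; all operations accept arbitrary cadence and the window
`n_min` scales accordingly), five sensor heights and thirty leaves — about
72 000 microclimate records and 430 000 leaf records, which keeps a full
pipeline run and the complete test suite at desk scale. The pipeline
inverts a seeded subsample (default cap 2000 records per species) for
calibration. Miscellaneous numerics: humidity predictions are clipped to
[0.01, 1] so D stays defined; quadratic roots use the stable
$q = -(B + \mathrm{sign}(B)\sqrt{B^2-4AC})/2$ form; wind interpolation
clamps beyond the outermost sensors rather than extrapolating (avoids
negative speeds); bins and windows are half-open with clock-aligned
boundaries; ΔT-measurement and g_s floors are stated above. Humidity
gap-fill models are per sensor height, with leaves taking the nearest
height's model — the height-resolved R² range of the fits is the evidence
the coupling supports this.

The pipeline stage order is simulate → derive → fit g_s → invert →
calibrate → predict → select windows → contrast → trait-swap: calibration
precedes window selection because selection compares observations against
predictions, and predictions made with an uncalibrated boundary-layer
coefficient would fail the slope gate wholesale — the calibrated
coefficient is what makes the selection meaningful.

# Known limitations

* The linearised balance is accurate for |ΔT| of a few degrees; large
  excursions incur linearisation error in the longwave term.
* No transient heat storage: τ is reported as a diagnostic, but leaf
  temperature is never integrated through time.
* Wet-leaf evaporation (fog, rain) is not modelled; real nighttime ΔT
  below air temperature from surface water has no counterpart here.
* The evaporation-dominated inversion ambiguity is intrinsic, not
  numerical: calibrations should use bright records only, as the package
  defaults do.
* The g_s model is a linear function of D alone — no light, temperature or
  hysteresis terms — matching the analysis it supports, not stomatal
  physiology in general.
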