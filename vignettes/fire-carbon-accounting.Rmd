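---
title: "Fire carbon accounting from LiDAR-Landsat fusion: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fire carbon accounting from LiDAR-Landsat fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(firecarb)
```

## The estimation problem

A large wildfire consumes part of the aboveground biomass (AGB) of the
landscape it burns; the released carbon is, to first order,

$$ C_r = A \times B \times f_c \times \beta $$

with $A$ the burned area (ha), $B$ the biomass density (Mg/ha), $f_c$
the carbon fraction of dry biomass (0.5 by default) and $\beta$ the
combustion completeness — the fraction of available biomass actually
consumed. The hard part is $B$ and $\beta$: biome-average fuel loads
ignore the spatial structure of real landscapes. `firecarb` implements a
bottom-up alternative: map AGB *before* and *after* the fire, difference
the maps, and read consumption, completeness and carbon release off the
difference, stratified by burn severity.

The chain has four stages.

1. **Plot-calibrated LiDAR biomass.** Postfire airborne LiDAR
   (height-normalized discrete returns, ~20 points/m² on a 30 m grid) is
   summarized into 41 per-cell metrics: height percentiles and moments,
   range-normalized intensity statistics, and pseudowaveform quantities
   (height of median energy, area under the canopy waveform — AUCW — and
   friends). A least-squares support-vector regression (LS-SVR) with a
   Gaussian kernel maps metrics to AGB, calibrated on 0.09 ha field
   plots in the unburned buffer around the fire. The expert feature pair
   is {AUCW, H50}: canopy material plus median canopy height.
2. **Fire-bias correction.** Standing dead trees (snags) keep the
   height percentile H50 high while the canopy material collapses, so
   the raw LiDAR model overestimates postfire biomass in the burn. Over
   unburned cells AUCW follows H50 along a tight power law
   $g(H_{50}) = a\,H_{50}^{\,b}$; inside the burn perimeter every cell
   is re-weighted by its canopy-material deficit,
   $w = \min(1, \mathrm{AUCW}_{obs}/g(H_{50,obs}))$, and the model is
   re-applied (not refitted) with $H_{50}^{corr} = w\,H_{50}$.
3. **Optical extrapolation.** The LiDAR biomass map trains two optical
   LS-SVR models (prefire and postfire six-band reflectance; features:
   bands 2–6, NDII and elevation) on ~514 pixels sampled by biomass
   histogram from unburned and low-severity cells only, so fire-damaged
   structure never contaminates the transfer. Wall-to-wall prediction,
   then a linear observed-vs-estimated bias correction per map, yields
   prefire and postfire biomass everywhere.
4. **Accounting and uncertainty.** Consumption maps are differenced for
   three method pairs (optical−optical, optical−LiDAR,
   optical−corrected LiDAR), aggregated per severity stratum
   (`Mg/ha × 0.09 ha × 10⁻⁶ → Tg`), converted to carbon (×0.5) and
   CO₂-equivalent (×44/12), and wrapped in a two-step error budget:
   $\sigma^2_{modeling} = \mathrm{RMSE}_1^2 + \mathrm{RMSE}_2^2$,
   stratum-mean standard errors that honour the spatial autocorrelation
   of the residuals through an exponential correlogram, and variances of
   differences of correlated estimates.

## What the synthetic scene emulates

No real acquisition ships with the package; `simulate_scene()` builds a
virtual landscape with known truth so the whole chain is testable:

* terrain from a smoothed Gaussian field (default relief 600–1600 m),
  with slope/aspect by Horn's method on the block-averaged DEM;
* a blob-shaped burn perimeter (~65% of the scene) surrounded by an
  unburned buffer holding the field campaign, with interior severity
  fractions 7.9 / 30.9 / 25.4 / 35.8 % (unburned / low / moderate /
  high);
* true prefire AGB from a truncated-normal landscape distribution
  (mean 195.8, sd 143.1, range 24.2–645.4 Mg/ha) modulated by vegetation
  type, and postfire truth `pre × (1 − cf)` with consumption fractions
  cf = (0, 0.30, 0.50, 0.85);
* per-cell tree lists: stand-size scaling couples tree diameter to
  stand biomass, heights follow a saturating height–DBH curve, per-tree
  biomass a power allometry, crown sizes a linear crown-diameter model,
  and a lognormal stand-level stocking multiplier (sd 0.45) scatters
  canopy cover between stands of equal biomass, as species mix and
  clumping do in real landscapes;
* point clouds: crown-envelope canopy returns (crown base rises from
  ~25% of height in open young stands to 50% in closed giants), ground
  returns, range-dependent intensity, Poisson counts at 20 points/m²;
* six-band reflectance as a linear mixture of vegetation, soil and char
  end-members driven by canopy cover, a weak elevation term, and
  Gaussian band noise (sd 0.01);
* a 71-plot campaign stratified over four stand-size classes (shares
  0.36/0.36/0.19/0.09 across 24–90–250–450–645 Mg/ha), with exactly two
  degraded GPS plots and four sparse low-cover plots that the filters
  remove, leaving 65.

### Fire effects and the scorch/consumption distinction

Fire converts a severity-dependent fraction of canopy returns to ground
returns. This *canopy-return removal* fraction — (0, 0.18, 0.32, 0.78)
by default — is deliberately smaller than the biomass consumption
fraction at low and moderate severity: surface and understory fuels
contribute substantially to consumed biomass but intercept few canopy
returns, while crown scorch drives return loss. In high severity the
snag mode keeps a sparse set of top-of-canopy returns (and always the
single highest), so H50 survives while canopy counts collapse — the
exact bias the correction exists for. These fractions were fixed once,
while building the generator, so that the estimator's recovered
combustion completeness brackets the true (0.30, 0.50, 0.85); they are
generator truth, not estimator inputs.

### What the generator does *not* emulate

No radiative transfer, no waveform LiDAR, no occlusion beyond the
statistical crown envelope, no topographic illumination, no clouds or
snow, no within-cell severity mixtures, no measurement error in the
field plots. A passing recovery test therefore demonstrates internal
consistency of the method under idealized structure, not performance on
real sensor data.

## Numerical and design choices

* **Percentiles** use linear interpolation between order statistics
  (R's default type 7); H50 feeds the headline model, so the convention
  is fixed and documented.
* **Pseudowaveform bins** default to 0.5 m; energy conservation is exact
  by construction and tested to 1e-9. The accumulated-intensity metrics
  are cumulative *fractions* of canopy intensity, keeping them invariant
  to point density; `dwCRS` divides the canopy reflection sum by returns
  per m² for the same reason. HOME interpolates the piecewise-linear
  cumulative energy over bin edges; the MacArthur–Horn profile clips
  log arguments at 1e-6. No canopy/ground reflectance correction factor
  is applied to intensity.
* **Kernel convention** is `K = exp(-d²/h²)` on standardized features;
  grids default to 15 log-spaced values, `h` in [0.1, 100], `γ` in
  [0.1, 1e4]. Cross-validation is tenfold, stratified by response
  deciles, seeded; on small samples the fold assignment is
  repeated (~400/n times) and the CV score averaged, because a single
  fold draw at n≈46 makes the (h, γ) choice unstable. Ties prefer the
  smaller γ, then the smaller h. R² is 1 − SSE/SST (it penalizes bias),
  relRMSE is 100·RMSE/mean(observed).
* **Stepwise selection** uses entry/exit p-values 0.05/0.10 on linear
  fits; the evolutionary search is a seeded genetic algorithm
  (population 30, generations 25, mutation 0.1) with linear-fit CV-MSE
  fitness. The expert subsets are the defaults everywhere.
* **H50 correction**: the weight is capped at 1 (fire only removes
  canopy), `g(H50) = 0` yields no correction, and the correction is
  applied to the entire burn perimeter, all severity levels. The
  power-law/weight-ratio construction is this package's committed
  interpretation of the correction; a multiplicative weight is the
  simplest form that leaves high-AUCW cells nearly untouched and zeroes
  fully defoliated ones.
* **GLCM textures** quantize to 64 levels by scene-wide min–max, use the
  symmetric co-occurrence matrix averaged over the four one-pixel
  offsets with mirrored edges, and define correlation as 0 for constant
  windows. Under this isotropic averaging, stripe patterns (which
  disagree on three of the four offsets) carry the maximal contrast
  among two-level patterns, slightly above the checkerboard. Textures
  are computed on demand but excluded from the default optical feature
  set: window-scale artifacts print through to biomass maps.
* **Prediction clamping**: biomass maps are clamped to the calibration
  response range. An RBF-kernel regression extrapolates erratically
  outside its training hull (predictions drift toward the bias term, in
  either direction), and no mapped pixel can credibly hold less biomass
  than the sparsest or more than the densest calibration stand.
* **Negative consumption pixels** (post > pre from independent model
  noise) are kept in stratum sums so totals stay unbiased; the negative
  fraction is reported as a diagnostic.
* **CO₂e** uses pure CO₂ stoichiometry (44/12). The per-car equivalence
  sometimes quoted alongside such totals needs an external per-vehicle
  factor and is not asserted anywhere.
* **Correlogram**: empirical correlations by offset classes, exponential
  model `ρ(d) = exp(-d/φ)` fitted by count-weighted least squares;
  stratum-mean variances evaluate ρ once per unique pair distance, which
  is exactly the n² double loop, just tabulated. Measurement, sensor and
  field errors are excluded from the budget as negligible against the
  modeling error. Pair covariances: the two optical maps share training
  reference and spatial structure, so their stratum means are combined
  with the empirical residual correlation; LiDAR- and optical-map errors
  are treated as independent.
* **Report rendering** rounds to 2 decimals only at output; internal
  arithmetic is full precision.

## Problem sizes

The default scene is 60×60 cells (3600 pixels, ~65 million simulated
returns streamed tile by tile, never held in memory), 71 plots, 514
sampled pixels — the full pipeline runs in about two minutes on one
core. The test suite works on smaller scenes (14–30 cells per side,
0.5–8 points/m²) chosen so that each property under test is still
exercised with comfortable margins; the end-to-end recovery test runs
the full default configuration.

## Known limitations

* The LS-SVR extrapolates poorly far outside its training hull (as any
  RBF-kernel method does): predictions decay toward the bias term. The
  stratified campaign and the on-manifold behavior of the H50 correction
  keep the corrected inputs inside or near the hull, but uncorrected
  postfire predictions in heavily burned cells are genuinely
  unreliable — which is the phenomenon the correction addresses.
* Combustion completeness is a ratio of two model-based totals; its
  uncertainty is dominated by the prefire map's bias, which the linear
  bias correction removes only globally, not per stratum.
* The chained-error identity assumes step-1 and step-2 errors are
  independent and both present in the final map. In a nested design the
  second model is trained on the first model's outputs, so the step-2
  RMSE already absorbs the non-transmitted (plot-level white) component
  of the step-1 error; the quadrature sum counts that component twice
  and is therefore a *conservative* estimate of the realized error
  (`emp² = comp² − 2σ²_white`). The replicate simulations confirm the
  bound and its order of magnitude; on real data the same conservatism
  applies whenever reference noise is partly white.
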