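---
title: "casafuse: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{casafuse: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casafuse)
```

casafuse estimates monthly net primary production (NPP) on a coarse
geographic grid while letting the *sub-pixel* composition of the landscape
influence the estimate. This vignette is the package's own account of the
science: the model, its assumptions, every tunable parameter and why its
default is what it is, the numerical choices, what the synthetic-data
generators do and do not emulate, and the limitations we know about.

## 1. The sub-pixel fusion chain

Coarse vegetation-index pixels (~0.004°, EVI-like, valid range −0.2…1) mix
the signals of every cover type inside them. The fusion chain unmixes them
in three steps:

1. **Fractional cover.** A fine categorical land-cover raster (cell size
   1/13 of the coarse cell by default) is aggregated by counting fine-cell
   *centers* inside each coarse pixel: the fraction of class *k* is
   (valid fine cells of class *k*) / (all valid fine cells). Center
   containment with half-open cells guarantees each fine cell is counted
   exactly once, so fractions sum to 1 on every pixel with any valid
   coverage.
2. **Pure pixels.** Coarse pixels whose dominant-class fraction is ≥ 0.9
   become point samples (at their pixel centers) of that class's EVI. The
   boundary is *inclusive*: a fraction of exactly 0.9 qualifies. One
   configurable threshold.
3. **Per-class interpolation.** Each class's samples are interpolated over
   the full grid by inverse-distance weighting (IDW),
   `z(x) = Σ wᵢ zᵢ / Σ wᵢ`, `wᵢ = d(x, xᵢ)^(−p)`, over the *k* nearest
   samples. IDW is an exact interpolator: a target coinciding with a
   sample returns the sample value (coincident samples return their
   mean — a deterministic tie rule that avoids division by zero). The
   result is the class's vegetation index "as if every cell were pure",
   clipped to the physical EVI range.

The power *p* is chosen per class by leave-one-out cross-validation:
each candidate in {1.0, 1.5, …, 4.0} is scored by the root-mean-square
prediction error (RMSPE) and the minimiser is kept, ties going to the
smallest power (smoother surfaces preferred when indistinguishable). The
cross-validation month is the class's greenest sampled month — the month
of maximum mean sample value — where spatial contrast is largest; tuning
per month instead is available but costs 12× the cross-validation work
for little change in smooth phenologies.

**Search neighbourhood.** A "variable search radius" is realised as
plain k-nearest-neighbours with `max_neighbors = 12` and no distance
cut-off. It is reproducible and parameter-light; with clustered pure
pixels it behaves like a variable-radius search (the radius adapts to
local sample density). Distances are planar in degrees on the model grid:
at the ~0.16° scene scale the metric distortion is far below the
interpolation error, and the choice keeps the interpolator identical to
how the grids themselves are indexed. Both are configurable in
`idw_params()`.

## 2. The light-use-efficiency model

Per class and month, on every pixel:

$$NPP = S_r \times IVI \times e_{max} \times T \times W$$

* `Sr` — total surface solar irradiance, MJ m⁻² month⁻¹ (an input
  raster; casafuse does not model terrain radiation).
* `IVI` — the per-class interpolated vegetation index from step 3.
* `e_max = 0.55` gC/MJ — maximum light-use efficiency. The equation
  multiplies *total shortwave* irradiance directly, so the
  shortwave→PAR conversion is absorbed into this constant; no separate
  0.5 PAR factor is applied. This is deliberate and matters when
  comparing `e_max` across models.
* `T` — temperature stress, the classic two-factor CASA form:
  `T1 = 0.8 + 0.02·topt − 0.0005·topt²` (sites with extreme optima pay a
  penalty) and a double-logistic `T2` that suppresses growth far from
  the optimum; the product is clipped to [0, 1]. `T` is unimodal in
  temperature with its peak near `topt`.
* `W` — moisture stress from the water balance below, in [0.5, 1]: even
  bone-dry soil retains `W = 0.5`, reflecting plants' access to residual
  moisture.

**Optimum temperature.** `topt` varies spatially in reality (0 °C in
polar regions to 30–35 °C in hot deserts). Without a published map, the
default derives it per pixel as the long-term mean temperature of the
climatologically warmest month, clipped to [0, 35] °C — the month of peak
canopy activity is a standard proxy for the growth optimum. A scalar or a
raster can be supplied instead.

### The three-layer water balance

Soil moisture lives in three stores — surface organic matter, topsoil,
subsoil to rooting depth — with field capacities set by soil-texture
class. The monthly step:

1. Evaporative demand `EET = min(PET, precip + stored water)` is met
   first from the month's precipitation, then drawn top-down from the
   store.
2. The remaining precipitation recharges the layers top-down until field
   capacity; the excess leaves as drainage.
3. `W = 0.5 + 0.5·EET/PET` (`W = 1` when `PET = 0`).

Water is conserved *exactly* each step:
`precip = Δstorage + EET + drainage`. The ordering — extraction before
recharge — is the one under which sustained `precip ≫ PET` drives the
store to full capacity, the physically expected fixed point; extracting
after recharge would leave the top layer perpetually depleted by ~PET
even in a rainforest climate.

`PET` is Priestley–Taylor:
`PET = 1.26 · Δ/(Δ+γ) · Rn/λ` with `γ = 0.066` kPa/°C, `λ = 2.45` MJ/kg
(1 kg ≡ 1 mm), and `Δ(t)` the saturation vapour-pressure slope. The
solar-irradiance input stands in for net radiation — an approximation
that overstates PET somewhat, which the [0.5, 1] floor on `W` cushions.

**Texture classes and capacities** (mm, layers 1/2/3): organic
40/150/300; 0–5 % clay 25/100/200 grading linearly to ≥30 % clay
15/60/120; lithosols 10/40/80. These are *configuration defaults* chosen
to span the plausible range from deep organic soils to skeletal
lithosols, not measurements; all are exposed. A `rooting_multiplier`
scales the subsoil capacity — 1.8 reproduces the published adjustment for
deep-rooted oak woodlands ("80 % more available soil water"); the default
1 leaves capacities untouched. We apply the multiplier to *capacity*
(storage available to roots) rather than to instantaneous extractability,
where a multiplier ≥ 1 capped by content would be a no-op.

**Spin-up.** Starting from half-capacity layers, 24 months of forcing
precede the first reported month, so the reporting years inherit a
climate-consistent moisture state. If the climate record starts exactly
at the reporting span, the first reporting year is repeated twice as
spin-up forcing — a documented fallback, second-best to real antecedent
climate.

### Compositing

Per-class NPP × fractional cover, summed per pixel: only cover types
present influence a pixel. When a class has no pure pixels its IVI (and
NPP) cannot be built; affected pixels' sums are *renormalised* by the
contributing fraction and flagged in a coverage-diagnostic raster —
renormalising treats the missing class as resembling the present ones,
whereas leaving the partial sum would bias the composite low by exactly
the missing fraction. The raw behaviour is available
(`renormalize = FALSE`). A landscape that is 100 % one class composites
*bit-identically* to that class's model output.

## 3. Tower evaluation

Eddy-covariance towers measure GPP; NPP is taken as a fixed ratio of it,
with 0.40–0.50 bracketing the published range for temperate ecosystems
(forest syntheses center on 0.47). Sites qualify only with ≥ 3 complete
calendar years (all 12 months present) so dormant seasons are
represented. The model is extracted at the tower either as the containing
pixel (`point`) or the mean of the 3×3 window (`mean3x3`, truncated at
grid edges), the latter mimicking a tower footprint of mixing air.

Ordinary least squares is fit with *measured* NPP as response and
*modelled* NPP as predictor; R² is the squared Pearson correlation and so
orientation-free; the slope/intercept orientation is documented rather
than load-bearing. Bias is `100·(mean modelled − mean measured)/mean
measured`. Zero-variance series leave R² missing, never zero. Groups
(site, season, cover) with fewer than 3 pairs report missing statistics
rather than disappearing. Seasons default to the meteorological map
(DJF/MAM/JJA/SON) — configurable, since no single convention is
universal.

Because Pearson correlation is invariant to positive rescaling of either
series, the evaluation R² is *provably identical* under any NPP:GPP
ratio; only the level (bias, slope) changes. `ratio_ttest()` quantifies
that level difference with a paired t-test, with interpretation left to
the user.

## 4. The synthetic scene generators

Every pipeline input can be generated with known ground truth, seeded and
pure in the configuration:

* **Landscape** — per-class smoothed Gaussian fields on the fine grid,
  class = argmax (threshold allocation): contiguous patches, soft
  boundaries, a realistic mix of pure and mixed coarse pixels. The true
  fractional cover is computed by an independent counting loop and
  returned — the oracle for the aggregation code.
* **EVI** — per-pixel mixture of per-class seasonal cosine phenologies
  (defaults: forest 0.45 ± 0.15 peaking July, grassland 0.35 ± 0.25
  peaking June, cropland 0.40 ± 0.30 peaking July) weighted by the true
  fractions, plus i.i.d. noise (sd 0.02, a plausible residual for
  composited index products), clipped to [−0.2, 1].
* **Climate** — sinusoidal annual cycles (temperature 8 ± 12 °C peaking
  July; precipitation 60 ± 30 mm/month peaking June; noise sd 1 °C and
  10 mm) — an interior mid-latitude seasonal climate; solar is a
  deterministic flat-surface clear-sky monthly total from solar geometry
  (transmissivity 0.75), which peaks in June at northern mid-latitudes.
  It stands in for a terrain radiation model, which is out of scope.
* **Towers** — sites at random valid pixels; GPP = composite NPP / 0.47
  (the published central ratio) + optional noise, floored at 0. At zero
  noise the generated towers are the exact inverse of the evaluation
  conversion, so pooled R² = 1 is the designed fixed point.

The reference study conditions — used by the acceptance tests and
`scripts/acceptance.R` — are a 40×40 coarse grid of 0.004° cells,
fine:coarse ratio 13, three cover classes, three reporting years with two
spin-up years, six towers. These sizes exercise every code path
(mixed/pure pixels, all seasons, spin-up, renormalisation) while keeping
a full pipeline run in seconds.

**What passing tests show — and don't.** The generators produce smooth
phenologies, stationary Gaussian patchiness, noise-free class labels and
a single constant NPP:GPP ratio. Real data have cloud-contaminated index
composites, land-cover misclassification and year-to-year change,
disturbance (harvest, fire, irrigation) decoupling EVI from NPP, and
tower footprints that are neither a pixel nor a 3×3 box. Green tests
demonstrate the pipeline's internal correctness — exact unmixing,
interpolation, conservation, recovery of planted truth — not skill
against real observations.

## 5. Numerical choices

* Grids are geographic degrees, pixel-is-area, row 1 at the north edge,
  half-open cells (west/north edges inclusive): every point belongs to
  exactly one cell, which makes center-counting and point extraction
  unambiguous.
* All computation is double precision; rasters are written as text with
  17 significant digits, so a write/read cycle is lossless.
* Spec equality between grids read from files uses a 1e-9° tolerance
  (geotransform float noise); resampling is nearest-neighbour by target
  cell center — values are never invented, which also keeps categorical
  rasters valid. No other kernel is offered.
* IDW coincident-point tolerance is 1e-12°; within it, samples are
  treated as co-located and averaged.
* The water budget closes to machine precision; tests assert 1e-9 mm.
* Degenerate inputs are flagged, not fatal, wherever the pipeline can
  proceed: classes without pure pixels are warned about and excluded
  (compositing renormalises), all-mixed landscapes yield empty sample
  sets with a warning, degenerate regressions report missing statistics.
* The constant-field *recovery* check samples fully pure pixels
  (threshold 1): a 90 %-pure pixel's mixed value still carries up to
  10 % of the other classes' signal, and an exact interpolator
  faithfully reproduces that contamination — recovery to 1e-6 is a
  property of truly pure samples, while the operational threshold stays
  at 0.9.

## 6. Known limitations

* Ten general cover classes by default; class sets are configuration —
  the scientific resolution of the analysis is bounded by how well broad
  classes capture regional vegetation differences.
* Land cover is static across years; `e_max` is one constant for all
  vegetation (C3 vs C4 differences, crop management, irrigation are
  invisible to the model).
* Solar irradiance is consumed as given and substitutes for net
  radiation in PET; no topographic shading, no elevation lapse
  corrections (an elevation raster is accepted but only passed through).
* Only geographic-degree grids; no reprojection. Planar degree distances
  in IDW are a scene-scale approximation.
* No heterotrophic respiration, carbon pools or nitrogen dynamics: the
  output is NPP, not NEP.

```{r example, eval = FALSE}
# end-to-end on the reference conditions
cfg <- scene_config(seed = 1)
scene <- make_landscape(cfg)
res <- run_fusion_casa(scene$landcover, make_evi(cfg, scene)$evi,
                       make_climate(cfg), make_soil(cfg),
                       classes = cfg$classes)
towers <- make_towers(cfg, res$composite, frac = res$frac)
evaluate_against_towers(res$composite, towers, ratio = 0.47)
```
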