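---
title: "Methods: light-use-efficiency GPP modelling at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light-use-efficiency GPP modelling at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasslue)
```

## The model and its assumptions

`grasslue` implements the light-use-efficiency (LUE) family of gross
primary productivity models: carbon uptake is proportional to the
photosynthetically active radiation a canopy absorbs, times a conversion
efficiency that environmental stress down-regulates,

$$\mathrm{GPP} = \mathrm{PAR}\times f\mathrm{APAR}\times
\varepsilon_{max}\, T_{s}\, W_{s}.$$

The assumptions this inherits are the standard ones of the family: a
linear APAR-to-carbon response within a bimonthly window; fAPAR adequately
proxied by an affine stretch of NDVI; temperature stress captured by a
single global quadratic response; water stress captured by the land
surface water index (LSWI) relative to its per-pixel seasonal maximum
rather than by vapour pressure deficit or soil moisture. Each bimonthly
map is a daily-rate value representative of its two-month window, so
intra-period variability (short droughts, heat spikes) is invisible by
construction.

### Parameters, units, defaults

| parameter | default | units | role |
|---|---|---|---|
| NDVI stretch | 0.03 – 0.96 | – | 2%/98% NDVI distribution thresholds |
| fAPAR range | 0.001 – 0.95 | – | theoretical extremes; values are clamped here |
| $T_{min}, T_{opt}, T_{max}$ | 0, 20.3, 48 | °C | quadratic temperature response |
| $\varepsilon_{max}$ | 1 (deferred) | gC m⁻² d⁻¹ MJ⁻¹ | biome factor, composed into metadata |
| storage step | 0.1 | gC m⁻² d⁻¹ | integer quantization of GPP |
| footprint radius | 250 | m | tower-to-raster comparison disc |
| gap-fill threshold | 20 % | – | tower series screening |
| DT/NT threshold | 3 | gC m⁻² d⁻¹ | daily partitioning-consistency filter |

The biome maximum-LUE table (`biome_lut()`) ships the eleven MOD17
globally adjusted values; grasslands are 0.860, which combined with the
0.1 storage step gives the grassland products their metadata scale of
0.086. Calibration never touches stored integers: `calibrate_grassland()`
masks and rescales metadata only, so uGPP and grassland GPP share pixels
exactly. This is deliberate — it lets any downstream land-cover product
recalibrate the same archive.

## Design choices where the design was open

**Temperature scalar outside its support.** The quadratic form is only
meaningful on $(T_{min}, T_{max})$. Below or at 0 °C the value is forced
to 0 (frozen canopies do not photosynthesize in this formulation); at and
above $T_{max}$ we also return 0, which extends the curve continuously —
the raw expression would change sign there and has no physical reading.
In-range values are clamped to $[0,1]$.

**The LSWI$_{max}$ window.** A single bimonthly composite has exactly one
LSWI per pixel, so "the maximum LSWI in a bimonthly period" cannot select
among values without a window convention. The default window is the
calendar year (the convention of the vegetation-photosynthesis model
family this model follows); `lswi_max()` also offers `"bimonthly"`
(identity, for sensitivity analysis) and `"full-series"`.

**The water scalar's algebraic form.** The printed form
$1-(1-\mathrm{LSWI})/(1+\mathrm{LSWI}_{max})$ is the default. It differs
from the more common $(1+\mathrm{LSWI})/(1+\mathrm{LSWI}_{max})$: under
the printed form a pixel at its seasonal LSWI maximum is still
down-regulated unless LSWI = 1. Both are available
(`w_scalar(..., formula = "printed" | "vpm")`) so the difference can be
quantified rather than argued.

**Compositing weights.** Bimonthly reflectance is a weighted average of
the up-to-four 16-day scenes in the window. Weighting "by cloud cover" is
directionally ambiguous; clearer scenes carry more information, so the
weight is $w = 1-\text{cloud\_cover}$, renormalized over the scenes where
the pixel is actually clear. If all contributing weights vanish at a clear
pixel the composite falls back to the unweighted mean (with a warning)
rather than dropping data.

**Annual accumulation.** Annual GPP is the mean daily rate over the
pixel's *valid* periods times 365. Requiring all six periods would empty
high latitudes wherever polar night or persistent cloud leaves a seasonal
gap; using valid periods keeps them populated at the cost of weighting the
observed season. Annual values are re-quantized at the cube's own scale,
so a period-constant cube annualizes exactly (1 gC m⁻² d⁻¹ → 365).

**R² definition.** Reports use the squared Pearson correlation, with
$1-\mathrm{SS}_{res}/\mathrm{SS}_{tot}$ about the 1:1 line available as a
clearly labelled alternative (`compute_metrics(..., r2 = "one_to_one")`).
Bias is model − observed. Footprint membership is pixel-center-in-circle —
unambiguous and checkable against brute-force enumeration, which the
tests do; area-weighted partial pixels would be precision theatre around
an empirically chosen 250 m radius.

**Even-count medians** use the midpoint of the two central values
(`stats::median`), declared so tests are bit-exact. **Gap-fill screening**
applies to the full series, matching the protocol's "total time series"
reading; a per-period variant is not enabled.

## Numerical conventions

* **Quantization**: stored = `round(value / 0.1)` with round-half-even
  (unbiased at step boundaries), unsigned-16-bit width, nodata 65535.
  Width is a declared choice: 6553.4 gC m⁻² d⁻¹ safely exceeds any
  physical daily GPP. Negative model values (possible only through driver
  artifacts) are clamped to 0 with a reported count.
* **Downscaling** of coarse drivers to the 30 m grid is a tensor product
  of 1-D natural cubic splines through cell centers (column pass, then row
  pass). Beyond the coarse hull, coordinates are clamped to the hull —
  nearest-value extension — so edges cannot overshoot; any interpolated
  PAR below 0 is clamped with a logged count. Constants are reproduced
  exactly and linear fields to ~1e-6; block-averaging the fine field back
  to the coarse grid recovers smooth fields within 5%.
* **Driver timestamps**: an 8-day temperature composite is assigned its
  window midpoint, a monthly radiation field its month midpoint;
  membership in a bimonthly period tests that midpoint against the
  half-open interval `[start, end)`, which is order-independent and
  assigns every timestamp exactly once.
* **Gap filling**: the production archive uses a seasonal time-series
  reconstruction that is out of scope here; `gapfill_passthrough()`
  honours its contract with a minimal causal rule — fill from the most
  recent valid same-bimonth value in past years only — and leaves the rest
  missing.
* **Degenerate inputs**: single-cell coarse rasters downscale to a
  constant; empty periods yield all-NA rasters with warnings; towers
  outside the raster extent, unknown land-cover codes and missing mask
  years raise errors naming the offender.

## What the synthetic scenes emulate — and what they do not

The generators (`gen_reflectance()`, `gen_climate()`,
`gen_grassland_mask()`, `gen_tower_series()`) reproduce the *statistical
structure* the pipeline assumes of its inputs: per-pixel seasonal
greenness sinusoids with hemisphere-dependent phase (NDVI spanning roughly
0.05–0.9 over the year), per-scene cloud gaps with recorded cloud cover,
smooth low-spatial-frequency temperature fields that cross 0 °C in winter
when the configured amplitude exceeds the mean, non-negative radiation
with summer maxima, spatially autocorrelated grassland masks hitting a
target share, and daily tower series as truth plus independent
day-time/night-time noise with gap-fill flags. Fixed seeds make every
generator bit-reproducible. The default study conditions are a
40 × 40-pixel 30 m scene over two years with an 8× coarser climate grid
— small enough that the full test suite runs in seconds while every
code path (compositing, downscaling, masking, validation) is exercised.

They deliberately do **not** emulate sensor physics: no atmospheric
residuals, BRDF effects, orbit-drift striping, sensor cross-calibration,
or realistic cloud spatial morphology, and the seasonal model is a
sinusoid, not phenology. Passing tests therefore demonstrate that the
*pipeline arithmetic* is correct and self-consistent — the known-answer
validation (noise-free towers generated from the forward model recover
r = 1, RMSE = 0 end to end) is a property of the code, not evidence about
accuracy on real landscapes, which depends on input quality the
generators idealize away.

## Known limitations

* A single global temperature optimum (20.3 °C) ignores biome- and
  pixel-level acclimation; LSWI-based water stress saturates in dense
  canopies and the printed formula never reaches 1 below LSWI = 1.
* The bimonthly window smooths over intraseasonal extremes, which biases
  annual totals in highly dynamic ecosystems.
* The causal same-season gap fill is a contract stand-in, far weaker than
  the production seasonal reconstruction it replaces.
* Raster georeferencing is a lightweight in-memory layer (grid descriptor
  + TIFF with JSON sidecar); there is no CRS reprojection, and tiling is
  pixel-block based rather than tied to a geographic graticule.
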