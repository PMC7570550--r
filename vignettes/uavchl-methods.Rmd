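---
title: "Estimating canopy chlorophyll from UAV RGB imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating canopy chlorophyll from UAV RGB imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavchl)
```

## The problem

Handheld SPAD meters give a reliable, unitless proxy for leaf chlorophyll,
but reading five points per plot across a trial is slow. Consumer RGB
cameras on low-altitude drones cover a whole trial in minutes, at the cost
of indirect measurement: chlorophyll must be inferred from canopy color.
`uavchl` implements that inference chain — band normalization, vegetation
indices, soil masking, plot aggregation, regression — together with the two
methodological questions that dominate its accuracy: how the choice of
feature-extraction approach (all pixels vs. green pixels; RGB vs. HSV) and
the flight altitude (ground sampling distance, GSD) change the
index–chlorophyll relationship.

## Radiometry

Raw 8-bit digital numbers (DN) confound color with illumination. All
indices are therefore computed on chromatic coordinates

$$R = \frac{r}{r+g+b},\quad G = \frac{g}{r+g+b},\quad B = \frac{b}{r+g+b},$$

which sum to one at every defined pixel. A pixel with $r+g+b=0$ carries no
chromatic information and is marked undefined rather than raising; undefined
values propagate through every later stage, and aggregations skip them.

The registry holds 18 indices (ExG, ExR, VDVI, ExGR, NGRDI, NGBDI, CIVE,
CRRI, VEG, COM, RGRI, VARI, ExB, MGRVI, WI, IKAW, GBDI, RGBVI), each a
closed-form function of the channel triple. Any pixel where a formula's
denominator vanishes (e.g. $R=G$ for WI) is undefined. Two definitions in
the source material are ambiguous, and both readings are exposed as
registry switches with the defaults documented in `?vi_registry`:

* **ExGR** defaults to the standard ExG $-$ ExR $= 3G - 2.4R - B$; the
  literal left-to-right reading of the printed expression
  ($G - 2.4R - B$) is available via `vi_registry(exgr = "literal")`.
* **RGRI** defaults to the printed $G/B$; the literature ratio $R/G$ is
  available via `vi_registry(rgri = "ratio_rg")`.

CIVE is implemented with the coefficient 0.8818 on $G$ exactly as printed
in its source table, although the cited literature uses 0.811; fidelity to
the tabulated formula wins.

For the HSV variant, the standard hexcone transform maps RGB to
$(H, S, V) \in [0,1]^3$ (red at $H=0$, green at $1/3$, blue at $2/3$), and
every index formula is evaluated with $(H,S,V)$ substituted positionally
for $(R,G,B)$. Hue is treated as a linear variable on $[0,1]$; no circular
statistics are applied, matching the analysis this package reproduces.

## Segmentation and the three approaches

Vegetation is separated from soil with the ExG $-$ ExR rule: a pixel is
green vegetation iff $\mathrm{ExG} - \mathrm{ExR} > m$ with margin $m = 0$
by default. Ties and undefined pixels are background — a conservative
choice that errs toward excluding soil. The margin is exposed because the
source protocol states only the comparison, not a numeric threshold.

Plot features are extracted three ways, always over the same ROI set:
approach 1 averages RGB-space indices over *all* plot pixels, approach 2
over green pixels only, approach 3 evaluates the indices on HSV channels
over the same green pixels. The plot statistic is the arithmetic mean over
qualifying pixels (median available), giving one regression point per plot.

## The scale-effect study

Coarser flight altitude mixes vegetation and soil inside each ground
pixel. `simulate_altitude()` models this as a Gaussian pre-filter (optical
blur, default $\sigma = f/2$ px) followed by block-averaging over
$f \times f$ windows (sensor areal integration); block means, not
nearest-neighbor sampling, because a real sensor integrates radiance over
its footprint. The altitude table
$\{25{:}0.006,\ 50{:}0.018,\ 75{:}0.021,\ 100{:}0.028,\ 125{:}0.034\}$ m
maps measured resolutions to integer factors $\{1,3,4,5,6\}$ as ratios to
the finest GSD.

`scale_study()` fits every index against SPAD at every factor and
approach; `scale_summary()` reports each index's peak factor (ties to the
lowest factor), the percentage of indices peaking at each factor, and
per-factor mean $R^2$. The regression statistic follows the source
convention: the printed formula is the Pearson correlation, labeled
$R^2$, so the package reports $r^2$ and exposes $r$; predictions are also
scored with the conventional $1 - SS_{res}/SS_{tot}$ under the separate
name `R2_ss`.

## Machine-learning estimation

Three regressors map the 18-index feature vector to SPAD: a
backpropagation network (`nnet`, one hidden layer), support-vector
regression (`e1071`, radial kernel) and a random forest
(`randomForest`). The source protocol fixes the evaluation design (70/30
split, ten-fold CV, $R^2$/RMSE/MAE, a $\pm 15\%$ band computed as
$|P - M| \le 0.15\,M$) but not the hyperparameters, so these are package
choices, all exposed through `ml_spec()`:

| method | defaults | rationale |
|---|---|---|
| BP  | 10 hidden units, linear output, standardized $x$ and $y$, decay $10^{-4}$, maxit 2000 | small single-layer net sized for tens-to-hundreds of plots; weight decay stabilizes the seeded fit |
| SVM | radial kernel, $C = 10$, $\varepsilon = 0.1$, internally standardized | standard $\varepsilon$-regression defaults for smooth low-noise targets |
| RF  | 500 trees, default `mtry` | forest size where OOB error has plateaued |

Every fit is seeded and deterministic; models persist via
`save_model()`/`load_model()` with bit-identical predictions. A
zero-variance target collapses all three methods to the constant
predictor (standardizing a constant is undefined, and the constant is the
unique least-squares answer). `predict_map()` applies a fitted model to
every green, feature-complete pixel, with an optional grid mode that
block-averages the per-pixel map.

## The synthetic scene generator

No field imagery is distributed with this analysis, so `generate_scene()`
constructs scenes with exactly the statistical structure the method
assumes: a grid of plots (default $4\times5 = 20$) on a red-dominant soil
background, where each plot's true chlorophyll sets the expected green
chromaticity of its canopy pixels through an affine map
$G = a + s\,\mathrm{chl}$. Defaults — SPAD range 25–55, $s = 0.003$,
$a = 0.30$, canopy fraction 0.7, chromatic noise sd 0.01, vegetation DN
sum 360 vs. soil 450 — are stated as assumptions about a mid-season maize
trial, not fits to any dataset; the source paper gives no quantitative
canopy-fraction or color-distribution values to copy. Vegetation is placed
as one contiguous blob per plot (seeded randomized region growth) with an
exact pixel count, because the scale effect under study is a
boundary-mixing effect and i.i.d. pixel placement would understate it.
Chromaticities are quantized to 8-bit DN on write, matching consumer
cameras; at the default brightness the quantization error on $G$ is below
0.005, the tolerance used by the signal-injection test.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: radiative transfer, BRDF and illumination
geometry, shadows, exposure variation, weeds, mosaicking seams, and any
chlorophyll signal in the red:blue balance. The last point matters for
interpretation: the generator splits non-green chromaticity between red
and blue at a chlorophyll-independent ratio (0.45, noisy per pixel), so
indices that contrast only red against blue (WI, IKAW) carry essentially
no signal at native resolution and their $R^2$ values are erratic by
construction. Mean-$R^2$ summaries over all 18 indices inherit that
noise at low degradation factors; per-index results for the
green-contrast indices are clean.

## Numerical and design choices

* **Degradation factor sets.** Property tests and the acceptance study use
  factors $\{1,2,3,4,6\}$, the divisors of the default plot geometry
  (48 px plots, 12 px gaps): at these factors ROI rectangles tile coarse
  pixels exactly, isolating pixel mixing from ROI re-rasterization. Factor
  5 misaligns the grid and adds a coverage artifact unrelated to the
  mechanism under test.
* **Monotone-degradation reference.** The mixing error of all-pixel NGRDI
  is measured against the vegetation-only value *at native resolution*.
  Re-deriving the vegetation value at each factor would let mask-mixed
  pixels drag the reference toward the all-pixel mean and mask the effect.
* **Scale-decline window.** The field protocol delineates ROIs on the
  50 m product (factor 3), so the monotone decline of approach-2 mean
  $R^2$ is asserted for factors strictly beyond 3. Below that, the mean is
  dominated by the no-signal ratio indices described above.
* **VARI boundedness.** $(G-R)/(G+R-B)$ is only bounded by 1 where
  $B \le \min(R, 2G)$ — e.g. $(0.1, 0.5, 0.4)$ gives VARI $= 2$ — so the
  bounded-index property is asserted on that (vegetation-like) domain,
  unconditionally for the six true normalized differences.
* **Ties and degenerate inputs.** Peak-altitude ties go to the lowest
  factor; a plot with zero green pixels is flagged and excluded from
  regression rather than contributing an NA; zero-variance regressions
  raise a degenerate-fit error, never a silent $R^2 = 0$; pixels with zero
  band sum or zero denominators become undefined, never Inf/NaN.
* **Rasters and geo-metadata.** Images are read and written as 8-bit PNG
  (exact DN round trip) and plain TIFF; pixel-size/origin metadata travels
  in a JSON sidecar rather than geo tags, and ROIs are carried as
  0-based, half-open pixel rectangles (GeoJSON polygons on disk).
* **Problem sizes.** The default test and acceptance runs use the 20-plot
  scene (252 × 312 px) for structural and scale checks and a 200-plot
  scene (306 × 606 px) for parameter recovery and the ML benchmark —
  sizes at which every quantity the package reports stabilizes while a
  full suite run stays around a minute.
* **Seeds.** Every stochastic operation takes an explicit seed (package
  default 20190908) and restores the caller's RNG state; identical
  config + seed reproduces scenes, splits, folds and fits byte-for-byte.

## Worked example

```{r example, eval = FALSE}
scene <- generate_scene(scene_config())
spad <- spad_plot_means(sample_spad(scene$truth))

features <- run_approach(scene$image, scene$rois, spad, approach = 2)
fit_linear(features$NGRDI, features$spad)

study <- scale_study(scene$image, scene$rois, spad,
                     factors = c(1, 2, 3, 4, 6))
scale_summary(study)$approach2$mean_r2

cv <- cross_validate(ml_spec("RF"), features, k = 10)
cv$pooled
```

## Known limitations

The generator's color model is a two-class mixture with affine
chlorophyll coupling; it cannot say which index wins on real maize, only
whether the pipeline's mechanics (masking, scaling, regression, mapping)
behave as the theory predicts. Findings that depend on real canopy optics
— which specific index is most scale-robust, the exact altitude where
$R^2$ peaks, field-level RMSE — require field imagery with co-located
SPAD readings. Shadow and grass pixels that pass the ExG $-$ ExR rule are
not modeled, and no radiometric calibration to reflectance is attempted:
the pipeline operates, deliberately, on normalized DN only.
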