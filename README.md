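# uavchl

Chlorophyll estimation from low-altitude UAV RGB imagery.

Plot-scale chlorophyll (SPAD scale) is the workhorse nitrogen-status
indicator in field trials, but meter readings are slow to collect. A
consumer RGB camera on a drone images a whole trial in one flight; the
catch is turning canopy color into chlorophyll reliably. `uavchl`
implements that full analysis chain for agronomists and phenotyping
groups:

* **Band normalization** to chromatic coordinates,
  `R = r/(r+g+b)` etc., so indices see color, not illumination.
* **18 RGB vegetation indices** (ExG, ExR, VDVI, ExGR, NGRDI, NGBDI,
  CIVE, CRRI, VEG, COM, RGRI, VARI, ExB, MGRVI, WI, IKAW, GBDI, RGBVI)
  as a registry computable per pixel in RGB-chromaticity or HSV space,
  with undefined-pixel propagation and documented handling of the two
  ambiguous formulas (ExGR, RGRI).
* **Vegetation/soil segmentation** with the ExG − ExR rule
  (`ExG − ExR > 0` ⇒ green vegetation).
* **Plot aggregation**: ROI-based extraction of per-plot index means
  over green pixels, joined with SPAD measurements.
* **Scale-effect analysis**: flight altitude is emulated by Gaussian
  blur + block-averaging (GSD ratios 1/3/4/5/6 for 25/50/75/100/125 m);
  per-index linear regressions against SPAD are compared across
  altitudes and across three extraction approaches (all pixels / green
  pixels / green pixels in HSV).
* **Machine-learning estimation**: backpropagation network, support
  vector regression and random forest from the 18-index feature vector,
  with 70/30 hold-out, ten-fold cross-validation, R²/RMSE/MAE and a
  ±15 % error band, plus per-pixel chlorophyll maps.
* **A synthetic scene generator** with ground truth (plots on soil,
  chlorophyll linearly driving canopy green chromaticity), so the whole
  pipeline is testable end-to-end without field data.

The regression statistic follows the source convention of reporting the
squared Pearson correlation as R²; the conventional 1 − SSres/SStot is
exposed alongside as `R2_ss`.

## Worked example

```r
library(uavchl)

# a 20-plot synthetic trial with known per-plot chlorophyll
scene <- generate_scene(scene_config())
spad  <- spad_plot_means(sample_spad(scene$truth))   # 5 pts x 3 reps

# approach 2: RGB indices over ExG-ExR green pixels
features <- run_approach(scene$image, scene$rois, spad, approach = 2)
fit_linear(features$NGRDI, features$spad)
#> <linear_fit> slope 171.9, intercept 0.135, R2 0.9986 (n = 20)

# how the regressions degrade as the ground pixel coarsens
study <- scale_study(scene$image, scene$rois, spad,
                     factors = c(1, 2, 3, 4, 6))
round(scale_summary(study)$approach2$mean_r2, 4)
#>     f1     f2     f3     f4     f6
#> 0.9582 0.9883 0.9855 0.9880 0.9730

# random-forest chlorophyll model, pooled ten-fold CV
cv <- cross_validate(ml_spec("RF"), features, k = 10)
cv$pooled
#> <eval_metrics> R2 0.9572, RMSE 1.9966, MAE 1.4854, within15 0.95 (n = 20)
```

The NGRDI fit says plot-mean NGRDI explains essentially all of the
between-plot SPAD variance on this scene (the generator injects the
signal, so this is the noise ceiling, not a field result). The scale
summary shows mean R² across all 18 indices at each degradation factor —
flat-to-declining as mixed soil/vegetation pixels blur the signal. The CV
metrics are in SPAD units: RMSE ≈ 2.0 against a 25–55 SPAD range, with
95 % of plots predicted within ±15 %.

`run_pipeline(pipeline_config(out_dir = "run1"))` chains all stages and
writes every artifact (scene, mask, R² tables, ML metrics, chlorophyll
map, `report.json`) into a directory.

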