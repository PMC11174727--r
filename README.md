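# bagseg

Bagged deep-learning semantic segmentation of crop canopies in field
phenotyping RGB imagery, with classical baselines, IoU evaluation, and a
synthetic field generator for fully reproducible experiments — all in R,
with no deep-learning framework dependency.

## The science

Field-based high-throughput plant phenotyping rigs photograph crop plots
from above; almost every downstream trait (canopy cover, vigor, senescence)
starts from a binary segmentation of *crop* vs *background* (soil, weeds,
shadow). Classical color thresholds are fast but brittle under illumination
change and late-season yellowing; texture classifiers help but are slow.
This package implements the comparison end to end:

* **Hue threshold** — a pixel is crop iff its HSV hue lies in a band
  `[2a, 2b]` degrees; the band is fit by exhaustive SSE grid search
  (`grid_search_hue()`, 30 candidate bands, deterministic tie-breaking).
* **GLCM random forest** — each pixel is classified from its R, G, B values
  plus five Haralick statistics (contrast, dissimilarity, homogeneity,
  correlation, ASM) of the gray-level co-occurrence matrix of its 7×7
  neighborhood (8 gray levels, four distance-1 offsets, border replication).
  Prediction is patch-to-pixel: a 256×256 patch costs exactly 65,536
  individual classifications.
* **Convolutional network** — a compact encoder–decoder with inverted
  residual blocks, multi-rate dilated spatial pyramid pooling, and a
  skip-connected decoder, trained with Adam on the cross-entropy loss

  J(w) = −Σᵢ Σₖ yᵢₖ log ŷᵢₖ   (sum over pixels i and classes k)

  over geometrically augmented patches, keeping the weights of the epoch
  with the lowest validation loss. Forward, backward, and optimizer are
  implemented in R over compiled im2col kernels; the test suite verifies the
  analytic gradients against finite differences.
* **Bagging** — `n` networks trained on distinct random train/validation
  splits of the same labeled pool (default 0.8, e.g. 600/150 from a
  750-patch pool), fused by per-pixel **majority vote**. If members err
  independently at rate p per pixel, a majority of 11 errs at the binomial
  tail rate — ≈ 0.0117 at p = 0.2, an order of magnitude below any single
  member.

Evaluation pools per-class intersection and union pixel counts over the test
set (micro-averaged IoU and mIoU; macro available). Two built-in
experiments: mIoU vs ensemble size (`estimator_curve()`) and mIoU vs labeled
sample size with Student-t bands (`sample_size_study()`; the 95% band
multiplier at 30 repeats is t(29) ≈ 2.045).

Because real phenotyping imagery cannot ship with a package, a deterministic
synthetic maize-field generator (`generate_field()`) provides labeled scenes
with the relevant signal structure: textured soil, lobed plant rosettes,
hue-shifting senescence, green weeds that stay in the background class, and
sunny/cloudy shade bands. See the vignette
(`vignettes/bagged-segmentation.Rmd`) for methods, design decisions, and the
generator's realism limits.

## Worked example

Twelve 64×64 synthetic scenes: nine to fit on, three held out. All numbers
below are the actual output of this code (R 4.x, single CPU; the whole block
runs in about four minutes, most of it the four network trainings).

```r
library(bagseg)

scenes <- generate_dataset(12, seed = 42, height = 64, width = 64)
pool <- tile_scenes(scenes[1:9], 64)
testset <- tile_scenes(scenes[10:12], 64)

# hue-threshold baseline
gs <- grid_search_hue(pool)
print(gs)
#> <hue_grid_search> best range [20, 80] grid units (SSE 471) over 30 combinations
evaluate_model(function(p) segment_by_hue(p, gs$best), testset)
#> <iou_report> IoU0 0.9693 IoU1 0.9574 | mIoU 0.9634

# GLCM random forest (300 sampled pixels per training scene)
rows <- sample_training_pixels(scenes[1:9], 300, seed = 1)
rf <- train_rf(rows, rf_config(n_trees = 50, max_depth = 12, seed = 2))
evaluate_model(function(p) predict_patch_rf(rf, p), testset)
#> <iou_report> IoU0 0.9624 IoU1 0.9475 | mIoU 0.9550

# one desk-profile network (64x64, width 0.25, 5 epochs, ~15 s)
est <- train_estimator(pool[1:7], pool[8:9], net_config(seed = 3))
glance(est)
#> # A tibble: 1 × 4
#>   n_parameters epochs best_val_loss final_train_loss
#>          <dbl>  <int>         <dbl>            <dbl>
#> 1         3230      5         2326.            1648.
evaluate_model(function(p) predict_patch(est, p)$mask, testset)
#> <iou_report> IoU0 0.8526 IoU1 0.7853 | mIoU 0.8189

# a 3-member bagged ensemble of the same network
spec <- bag_spec(3, 0.8, split_seed = 9, estimator_config = net_config(seed = 3))
ensemble <- train_ensemble(pool, spec)
evaluate_model(function(p) ensemble_predict(ensemble, p), testset)
#> <iou_report> IoU0 0.8945 IoU1 0.8458 | mIoU 0.8702
```

Two honest readings of these numbers. First, bagging three estimators lifts
mIoU by 0.05 over the single network — the ensemble effect the package is
built around, visible even at this tiny scale. Second, the color baselines
*beat* the desk-scale network here: synthetic scenes are nearly
color-separable by construction, which favors hue- and RGB-based models,
and the desk profile (width 0.25, 5 epochs) is deliberately small. The
network's advantages — robustness to hue drift and texture confusion — are
what the full profile (`net_config("full")`) targets on real imagery.

Fitted objects are tidyverse-friendly: `tidy()`, `glance()`, `autoplot()`
work on grid searches, estimators, and both experiment curves, and
experiment results are tibbles. A YAML-configured driver
(`run_pipeline()`, CLI in `inst/cli/bagseg.R`) runs
synthesize → tile → fit → evaluate end to end into a timestamped run
directory with a structured log and a performance table.

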