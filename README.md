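# uavyield

Plot-scale grain-yield prediction from multi-temporal UAV imagery, in R.

Breeding and agronomy trials increasingly fly small UAVs carrying a
five-band multispectral sensor (blue, green, red, red-edge, near-infrared)
and an RGB camera over replicated field plots. `uavyield` turns the
resulting co-registered rasters into a per-plot feature table and predicts
harvested grain yield with random-forest regression. It is aimed at crop
phenotyping groups who have plot polygons, per-stage reflectance/RGB/DSM
rasters and harvest records, and want a tested, reproducible path from
pixels to yield metrics — plus a synthetic field-trial generator so the
whole pipeline can be exercised and validated without any field data.

## What it computes

**Features, per sample and growth stage**

- Band reflectance means (B, G, R, RE, NIR).
- Sixteen vegetation/color indices, e.g. NDVI = (NIR − R)/(NIR + R),
  EVI = 2.5(NIR − R)/(NIR + 6R − 7.5B + 1), SAVI, MTVI2, red-edge indices
  NDVI_RE, MSR_RE, CI_RE = NIR/RE − 1, and RGB color indices on normalized
  digital numbers r = R/(R+G+B) etc.: ExG = 2g − r − b, VARI, NDYI, ...
- Eight GLCM texture statistics (mean, variance, homogeneity, contrast,
  dissimilarity, entropy, second moment, correlation) from a 3×3 moving
  window with a 1-pixel co-occurrence shift, per multispectral band —
  280 texture features per sample over seven stages.
- Three agronomic trait parameters: canopy height CH = DSM − DEM,
  fractional vegetation cover FVC = 100·c/n from an SVM crop/soil
  classification, and canopy volume VOL = Σ A_i·CH_i over crop pixels.

**Ground truth.** Harvest records are standardized to 13% grain moisture:
Ym = 10000·(G/A)·(1 − C)/(1 − 0.13) in kg/ha.

**Models.** Random forests (500 trees, library defaults otherwise) under
four protocols: single features, exhaustive evaluation of all 2^k − 1
feature subsets of a family, per-growth-stage vs entire-period models, and
cross-cultivar transfer (train on one cultivar, test on the other, average
both directions). Accuracy is reported as Pearson R, R² = 1 − SSE/SST,
RMSE and RRMSE = 100·RMSE/mean(observed).

## Worked example

```r
library(uavyield)

# a 2-cultivar x 4-N-rate x 6-replicate trial, 7 flight dates, 10 cm pixels
des <- experiment_design(ground_resolution = 0.1)
ds  <- simulate_dataset(des, seed = 3)

feats  <- build_feature_table(ds, n_train = 300, seed = 3)
yields <- with(ds$harvest, data.frame(
  sample_id = sample_id,
  Ym = standardize_yield(grain_weight_kg, area_m2, moisture_pct / 100)))
ft <- widen_feature_table(feats, yields, ds$plots)
ft
#> <feature_table> 96 samples x 448 feature columns (7 stages)

fit_predict(ft, c("CH", "FVC", "NDVI_RE", "EVI"), config = model_config(seed = 3))
#> <uav_eval> {CH, FVC, NDVI_RE, EVI} | test R2 0.573, RMSE 717 kg/ha, RRMSE 9.78%

cr <- combination_search(ft, c(feature_families()$REVIs, feature_families()$AgTP),
                         config = model_config(seed = 3))
head(cr$results, 3)
#>   subset size    RRMSE        R2         R     RMSE
#> 1    VOL    1 8.732223 0.6598451 0.8380261 639.9558
#> 2 CH+VOL    2 8.997839 0.6388368 0.8254557 659.4219
#> 3     CH    1 9.359651 0.6092073 0.8007343 685.9380
```

The evaluation holds out a third of the samples (stratified by cultivar ×
nitrogen rate, with each subplot kept on the same side as its parent
plot); `RRMSE` is the held-out error relative to mean observed yield, so
the best three-index search above predicts yield to within ~9% of the
mean. `combination_search` fits every non-empty subset of the family (63
for the 6 variables here) under one fixed split and ranks them by test
RRMSE.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/uavyield.R` (`simulate` and `run` subcommands).

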