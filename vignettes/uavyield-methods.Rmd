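---
title: "uavyield: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{uavyield: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(uavyield)
```

This vignette documents what `uavyield` computes, the assumptions behind
the synthetic field-trial generator, and the choices made where the design
was genuinely open. It states no empirical number that the package's test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

A replicated small-plot trial (two wheat cultivars × four nitrogen rates ×
six replicates; 48 main plots of 3 × 13.7 m, each with an interior 1 × 1 m
subplot, 96 samples in total) is overflown at seven growth stages from
jointing to maturity. Each flight yields a co-registered set of rasters: a
five-band multispectral reflectance stack (B, G, R, RE, NIR in [0, 1]), an
RGB image, and a canopy digital surface model (DSM); a single bare-soil
digital elevation model (DEM) is acquired before emergence. The goal is to
predict the standardized grain yield of each sample from image features,
and to quantify which features, stages and sensors carry the signal.

The pipeline deliberately starts *after* photogrammetry: mosaicking,
radiometric calibration and geometric registration are upstream concerns,
and mis-registered inputs are rejected rather than resampled.

## Feature extraction

**Spectral.** Per-plot features are the five band-reflectance means and
sixteen vegetation/color indices. Multispectral indices use band
reflectances; color indices use normalized digital numbers
r = R/(R + G + B), etc., the standard convention for these published
indices. Two open choices:

- *Mean-of-index vs index-of-mean.* By default each index is evaluated per
  pixel and averaged over all in-plot pixels, preserving within-plot
  nonlinearity; evaluating the index once on the plot-mean spectrum is
  available via `convention = "index_of_mean"` for sensitivity analyses.
- *Degenerate pixels.* A pixel where an index's denominator vanishes (for
  VARI, g + r − b = 0) gets NA for that index and drops out of the plot
  mean; if more than half of a plot's pixels are degenerate the plot value
  is reported missing. Soil pixels are *not* masked out of spectral
  features — the plot mean is over all pixels inside the polygon.

Two published forms are worth noting: MSR_RE = (NIR/RE − 1)/(√(NIR/RE) + 1)
and MTVI2 = 1.5[1.2(NIR − G) − 2.5(R − G)] / √((2NIR + 1)² − (6NIR −
5√R) − 0.5), i.e. both carry a radical that sloppy transcriptions drop.
The test suite checks EVI against its two-band variant EVI2 near EVI2's
design condition (B ≈ 0.48R, agreement within 0.05) as a transcription
guard.

**Texture.** Gray-level co-occurrence (GLCM) statistics are computed per
multispectral band: the band is linearly quantized to 32 gray levels over
its global min–max, and for every pixel a 3 × 3 window with a 1-pixel
rightward shift (symmetric accumulation) yields a co-occurrence
distribution from which the eight Haralick statistics are evaluated
(7 stages × 5 bands × 8 = 280 texture features per sample). Choices:

- 32 levels is a documented, configurable default; commercial tools vary
  (64 is also common) and the choice mainly rescales MEA/VAR.
- Windows are clipped at raster edges rather than padded — no pixel values
  are invented.
- A single shift direction is the default; averaging over a direction list
  is available via `glcm_config(directions = ...)`.
- GLCM correlation is defined as 0 when either marginal standard deviation
  vanishes (constant window), keeping the statistic finite.

The per-pixel pass runs in compiled code; the R-level `glcm()` /
`texture_vector()` pair is the reference definition and the test oracle.

**Agronomic traits.** CH = DSM − DEM per pixel, negative values clipped to
zero (surface noise can put the canopy model below the soil model); the
plot CH is the mean over all in-plot pixels (a crop-only mean is a config
switch). FVC = 100·c/n from a supervised crop/soil classification — an SVM
(radial kernel) on the five band reflectances, trained on labeled pixels,
with a simple NDVI-threshold classifier available as a second method.
VOL = Σ A_i·CH_i summed over crop pixels, as the summation bound `c`
indicates; an all-pixel variant is behind `crop_only = FALSE` since the
bound is ambiguous in parts of the literature.

**Yield.** Ym = 10000·(G/A)·(1 − C)/(1 − 0.13) kg/ha standardizes grain
weight G (kg) over area A (m²) at moisture fraction C to the 13% wheat
standard. Harvest CSVs may carry moisture as percent (`moisture_pct`) or
fraction (`moisture_frac`); the header disambiguates.

## Models and evaluation protocols

A random forest with 500 trees (all other hyperparameters at the
`randomForest` defaults: mtry = max(p/3, 1), nodesize 5) is trained on 2/3
of the samples and evaluated on the held-out 1/3. Reported metrics are
Pearson R, R² = 1 − SSE/SST on the test set (the squared Pearson
correlation is reported alongside, since both conventions circulate),
RMSE, and RRMSE = 100·RMSE/mean(observed).

Protocol choices that were genuinely open:

- *Split.* The test third is sampled within each cultivar × nitrogen
  stratum so it covers the design, and by default the sampling unit is the
  main plot so a subplot never lands opposite its parent (plot/subplot
  leakage would otherwise flatter every metric). Treating the 96 samples
  as fully exchangeable is available with `grouped = FALSE`.
- *Combination search.* All 2^k − 1 non-empty subsets of a feature family
  are evaluated under one fixed split and seed — re-randomizing per subset
  would let split noise dominate the ranking. Ties break toward fewer
  variables, then lexicographic names. Families above 25 variables are
  refused unless a `max_subsets` budget is given, in which case subsets
  are sampled.
- *Stages.* "Entire growth period" means concatenating the per-stage
  columns of the chosen features (7× the columns of a single-stage run).
- *Cross-cultivar transfer* trains on all samples of one cultivar and
  tests on all of the other, both directions, and reports the mean — which
  makes the result invariant to relabeling the cultivars.

## The synthetic trial generator

No field imagery ships with the package; the generator produces datasets
with the statistical structure the analysis assumes, so every stage is
testable offline. What it emulates — and what it does not — determines
what a passing test suite can claim.

**Latent growth.** Each plot follows logistic height and cover curves over
the stage axis, a senescence curve rescaled to zero at jointing, and a
chlorophyll proxy that declines with senescence. Nitrogen acts through a
saturating response N/(N + 120 kg/ha) on the height, cover and chlorophyll
asymptotes. One cultivar carries a +15% height offset and a one-stage
earlier phenology so the cross-cultivar protocol has a real difference to
detect. Plot-to-plot variation is a shared log-normal "fertility" effect
(SD 0.10) times small trait-specific effects (SD 0.02); the shared effect
is what gives the trait–yield correlations their realistic strength —
with independent per-trait effects the peak-height–yield correlation
drops to ~0.6, whereas field trials (and this generator's defaults)
sit near 0.8.

**Yield.** A deterministic function of peak height, peak cover and the
seasonal chlorophyll mean (300 + 5000·CH + 3000·cover + 3000·chl, kg/ha)
plus multiplicative Gaussian noise with 8% CV, giving 5–11 t/ha — the
range of a high-yielding winter-wheat trial. Subplots share the parent
plot's latents but draw independent yield noise, matching how paired
plot/subplot harvests behave.

**Scenes.** Soil/vegetation assignment thresholds a spatially correlated
Gaussian field (correlation length 10 cm) at the per-plot cover quantile,
so the realized vegetation fraction matches the latent cover to within
1/n while leaving patchy structure for texture features. Vegetation
reflectance is linear in the chlorophyll proxy and senescence — NIR rises
with chlorophyll and falls with senescence, red the reverse — over a
documented flat soil spectrum; per-pixel noise SD is 0.008 reflectance
units. The DSM adds the per-pixel canopy height on vegetation pixels plus
1 cm Gaussian surface noise to a gently sloping DEM. RGB digital numbers
are the visible bands under a gain of 2.2, quantized to 8 bits.

**What it does not emulate:** photogrammetric artifacts (doming, smearing,
shadow), atmospheric and BRDF effects, weeds and lodging, spatially
autocorrelated fertility *gradients* (the fertility effect is i.i.d. per
plot), and measurement error in plot geometries. Recovery results on
synthetic scenes therefore demonstrate that the *computations* are
correct and well-conditioned, not that field accuracy will match.

## Numerical and I/O choices

- Rasters are TIFFs with a JSON sidecar for georeferencing (origin at the
  upper-left pixel corner, map y up, row-major storage). Continuous
  layers use 16-bit samples; reflectance is generated on the k/65535 grid
  (step 1.5e-5, far below the 0.008 spectral noise), which makes
  write/read round trips bit-identical; packed layers such as elevation
  round-trip within scale/65535 (~2e-5 m here).
- Plot membership is by the pixel-center rule (a pixel belongs to the
  polygon containing its center), matching integer pixel counting in the
  cover and volume formulas; plot edges are laid on pixel boundaries so no
  center is ambiguous.
- All randomness flows through explicit integer seeds via `withr`
  (layout, latents, per-stage rendering, classifier sampling, splits,
  forests); the same seed reproduces a dataset byte for byte.

## Problem sizes in the tests

The test suite and acceptance script run the full 48-plot design at 10 cm
ground resolution (the coarsest that divides the 3 × 13.7 m plots), a
285 × 857 pixel field — large enough for 2500-pixel subplots and stable
texture statistics. The stochastic recovery suite uses ten seeds of a
3-replicate variant (24 plots, 48 samples) without texture features,
since the searched family (red-edge indices + agronomic traits) uses
none. The exhaustive-search acceptance path evaluates a k = 10 family
(1023 forests); the k = 19 family (524,287 subsets) is enumerated and
counted exactly, with full evaluation available under a `max_subsets`
budget — evaluating all 524,287 forests is a multi-hour batch run by
design, not a test.

Two stochastic properties are asserted as means over the ten seeds rather
than per seed: cross-cultivar RRMSE exceeds the pooled-split RRMSE (a
direction, not a magnitude), and the entire-period model beats the *best
per-stage mean* RRMSE. The second comparison is deliberately against
per-stage means across seeds: taking each seed's minimum over seven
stages first would build selection bias into the baseline.

## Known limitations

- The SVM classifier is retrained per scene from sampled labels; there is
  no cross-stage model reuse or active selection of training pixels.
- The combination search treats the fixed split as ground truth for
  ranking; a nested or repeated-split ranking would be slower but less
  tied to one partition.
- Texture features are computed on the multispectral bands only, and only
  one co-occurrence shift is used by default.
- GeoTIFF georeferencing is carried in a JSON sidecar, not in embedded
  tags; consumers outside this package will see a plain TIFF plus
  sidecar.
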