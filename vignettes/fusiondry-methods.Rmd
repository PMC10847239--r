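---
title: "Methods: multi-sensor fusion modeling of shrimp drying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sensor fusion modeling of shrimp drying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fusiondry)
```

## Scope and model

`fusiondry` implements a chemometric pipeline that predicts the moisture
content (MC, mass fraction of water) of shrimp during solar drying from
two non-destructive sensors: a visible/near-infrared hyperspectral camera
(224 bands, 397.66–1003.81 nm) and a 10-sensor metal-oxide electronic
nose. The reference MC is gravimetric,
\(X = (m_2 - m_3)/(m_2 - m_1)\) (`compute_mc()`), carried internally as a
mass fraction in \([0, 1]\) and presented as a percentage only at the
reporting layer.

The modeling chain per sample is:

1. **Reflectance correction** (`reflectance_correct()`):
   \(R = (R_\mathrm{raw} - R_\mathrm{black})/(R_\mathrm{white} -
   R_\mathrm{black})\), per pixel per band.
2. **ROI segmentation** (`segment_roi()`): Otsu threshold on the band
   nearest 685.5 nm (the wavelength of maximal shrimp/background
   contrast), brighter side is foreground, largest connected component
   kept.
3. **Raw variables**: the 224-band mean ROI spectrum
   (`mean_spectrum()`); 18 colour moments — mean, population SD and
   skewness of R, G, B, H, S, V over the masked RGB composite
   (647/550/460 nm) — plus 8 GLCM texture statistics (contrast,
   correlation, energy, homogeneity, direction-averaged at distance 1) of
   the PC1 and PC2 score images of the masked cube, 26 image variables in
   all (`image_feature_vector()`); and the 10 steady-state E-nose
   responses.
4. **Preprocessing** (`apply_recipe()`): row-wise SNV and Savitzky–Golay
   derivatives in the six named composites RAW, SNV, FD-SNV, SD-SNV,
   SNV-FD, SNV-SD.
5. **CARS variable selection** (`cars_select()`) per block.
6. **PLSR** (`fit_plsr()`, NIPALS, autoscaled predictors) with the
   latent-variable count chosen by cross-validated RMSE
   (`choose_lvs()`).
7. **Fusion** (`run_fusion_pipeline()`): pixel-level (concatenate
   preprocessed blocks), feature-level (concatenate CARS selections) and
   decision-level — ordinary least squares of the calibration references
   on the per-block calibration predictions,
   \(y = b + k_1 x_\mathrm{spectra} + k_2 x_\mathrm{image} +
   k_3 x_\mathrm{e\text{-}nose}\) — for the HSI-only and the
   HSI + E-nose block sets.
8. **Evaluation** (`evaluate_predictions()`): \(R^2\), RMSE on
   calibration and validation sets, and RPD = SD(y_val)/RMSEV. These
   satisfy the identity \(\mathrm{RPD}^2 (1 - R^2_v) = n/(n-1)\), which
   the tests exploit.

Assumptions: MC varies smoothly and monotonically with drying time;
reflectance is linear in the calibration frames; the ROI is a single
connected bright object on a darker background; sensor responses are
steady-state scalars.

## The synthetic-data generator

The original drying experiment is not publicly deposited, so the
generator (`generate_dataset()`) is a first-class, tested module that
produces data with the statistical structure the analysis assumes. Its
defaults are the study conditions:

* **Design**: 13 stages (boiled = 0 h, then 1–12 h) × 8 replicates = 104
  samples.
* **Drying curve** (`mc_curve()`): a normalized logistic in time pinned
  exactly to 72.75 % MC at 0 h and 15.67 % at 12 h. No functional form is
  published for the curve, so the logistic midpoint was set at 4 h and
  the time scale at 2 h, once, so that the maximum drying rate falls at
  4 h at roughly 8.3 percentage points per hour with slow phases before
  2 h and after 7 h — the reported kinetics. Between-replicate SD is
  0.015 mass fraction, a typical within-stage spread for biological
  replicates of this size.
* **Cubes** (`generate_cube()`): an elliptical shrimp (shrinking
  slightly as it dries) on a dark background. Foreground reflectance is
  a smooth baseline (dip near 480 nm, visible rise, 700–900 nm plateau,
  gentle roll-off past 930 nm) minus Gaussian water-absorption bands at
  750 and 960 nm whose depth is `depth_scale * mc` — strictly increasing
  in MC — with the visible range darkened progressively as the sample
  dries (`darkening`, default 0.35 at full dryness). Noise terms map
  onto the preprocessing steps that exist to remove them: a per-sample
  log-normal multiplicative scattering factor (SD 0.08) and additive
  offset (SD 0.03) motivate SNV; a smooth within-shrimp texture field
  that strengthens with dryness feeds the GLCM features; white sensor
  noise (SD 0.004) motivates smoothing. The wavelength axis is 224
  linearly spaced points over 397.66–1003.81 nm; the instrument's true
  band centers are unpublished. The default cube is 96 × 96 px — the
  analysis operates on ROI statistics, so desk-scale spatial sampling
  loses nothing structural; size is configurable.
* **E-nose** (`generate_enose()`): each sensor is a saturating
  (Michaelis–Menten-like) response to a volatile latent variable that
  grows as moisture is lost, with fixed per-sensor constants (baseline,
  amplitude, sign, half-saturation), a per-sample log-normal gain drift
  (SD 0.02) and additive noise (SD 0.01). Transient sampling curves are
  not simulated: the pipeline only consumes the steady-state vector.
  Whether E-nose replicates pair 1:1 with imaging replicates is not
  stated in the source experiment; the generator assumes 1:1 pairing.
* With all noise switched off, every generated quantity is an exact
  closed form (`shrimp_spectrum()`, the sensor model), which the tests
  compare against independent evaluations of the same formulas.
* Every ground-truth parameter, including per-sample seeds, is recorded
  in a manifest (YAML on export) so recovery tests can read it.

What the generator does **not** emulate: real shrimp optics (pigment
chemistry such as astaxanthin, specular highlights, shape variability),
volatile chemistry, sensor cross-sensitivities, or ambient-humidity
artefacts. Passing tests therefore demonstrate that the pipeline
recovers structure it is designed for — not field performance on real
shrimp; on real data the single-block and fused accuracies would be
lower and closer together.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window`, `polyorder` (S-G) | 11, 2 | bands | Unpublished in the source; 11 points ≈ 30 nm on a 224-band axis smooths noise without washing out the 960 nm band. Blocks narrower than the window (10-sensor E-nose) fall back to a 5-point window. |
| `levels`, `d` (GLCM) | 32, 1 | grey levels, px | Quantization is min–max over the mask; 32 levels keeps co-occurrence matrices well-populated at ROI sizes of a few thousand pixels. `d = 1` compares adjacent pixels. |
| `cum_var` (PCA images) | 0.99 | — | Retain PCs to 99 % cumulative variance, but always at least PC1 and PC2, which are the two texture sources. |
| `n_runs`, `cv_folds`, `mc_fraction`, `max_lv` (CARS) | 50, 5, 0.8, 10 | — | The canonical Monte Carlo scheme; the exponential schedule retains all p variables at run 1 and two at the last run. |
| `max_lv` (PLSR) | 10 | — | Matches the observed ceiling in this kind of spectral MC model; configurable. |
| `ratio`, `method` (split) | 3, systematic | — | Rank samples by MC and send the 3rd of every 4 to validation, so the validation range sits inside the calibration range. |
| `recipes` (fusion defaults) | FD-SNV / FD-SNV / SNV | — | The per-block recipe choices carried into fusion, overridable; the screening grid (`screen_recipes()`) evaluates all six per block. |

## Numerical choices and degenerate inputs

* **Calibration clipping**: noise can push \(R\) outside \([0, 1]\);
  values are clipped to \([0, 1.5]\), the clipped fraction is recorded,
  and more than 5 % clipping is an error. Reference frames with
  `white − black` below 1e-6 raise an error naming the offending band.
* **Band lookup** is nearest-neighbour with ties to the lower index; no
  interpolation. Array coordinates are row-major, origin top-left.
* **Skewness** is the signed cube root of the third central moment
  (standard colour-moment convention); third moments below 1e-14 are
  snapped to zero because the cube root amplifies floating-point
  cancellation.
* **GLCM correlation** of a zero-variance region is defined as 0 (the
  0/0 case); only pixel pairs with both ends inside the mask count.
* **SNV** rejects zero-variance rows by id; it is fit per row, so it can
  never leak validation information.
* **CARS** draws variables without replacement with probability
  proportional to |coefficient|; zero-weight variables are never
  retained. Ties in minimal RMSECV break toward fewer variables, then
  the earlier run. The retained-count schedule guards its `ceiling()`
  with a 1e-9 epsilon against floating-point overshoot.
* **Cross-validation folds** are contiguous-stratified by the response:
  samples are sorted by MC and fold labels dealt within consecutive
  groups, so every fold spans the drying range and no drying stage is
  held out wholesale. Fold assignment is seeded and logged.
* **Decision fusion** uses unconstrained OLS (no nonnegativity is
  imposed on the weights); exactly collinear block predictions trigger a
  1e-8 ridge fallback, which returns the minimum-norm exact solution,
  with a warning.
* **PLSR** autoscales predictors (centre + unit variance) because the
  blocks mix units (reflectance, colour moments, conductance ratios);
  scaling statistics come from the fitting rows only. NIPALS stops early
  if the response residual loses covariance with X and pads the
  coefficient path, so cross-validation can always score 1..`max_lv`.

## Open design decisions

Where the source description was ambiguous, the package commits to one
choice and records it here:

* The segmentation threshold at 685.5 nm is unspecified → parameter-free
  Otsu on the *calibrated* band, largest component kept.
* Whether texture PCA runs on the spectral bands of the masked cube or
  on the RGB composite is ambiguous → spectral-band PCA, since the score
  images then summarize the full spectral covariance.
* Hyphenated recipe names are read left-to-right as application order
  (FD-SNV = derivative first). The alternative order is available as its
  own recipe name.
* The stated 3:1 split (84 + 28) is inconsistent with 104 samples;
  the package uses a systematic 3:1 split by MC rank, giving 78/26.
* Derivative recipes on the heterogeneous 10-sensor block are of
  doubtful chemical meaning but are implemented (5-point window) because
  the screening grid includes them.
* CARS selects on the preprocessed block used for modeling (not the raw
  block).
* One split is reused across all model variants of a run, so rows of the
  report are comparable.

## Problem sizes used by the test suite

The suite exercises exact small oracles (2-pixel moments, 2×2 GLCM,
20×5 PLSR against least squares), planted-variable CARS recovery
(n = 80, p = 100, 2 informative variables, 20 seeds), and ten end-to-end
replicates of the full default experiment (104 samples, 96×96×224
cubes). These sizes were chosen as the smallest that still exercise every
code path at full fidelity; the experiment itself is the study-scale
design.

## Known limitations

* ENVI I/O covers the plain hdr + binary dialects (BSQ/BIL/BIP, float32
  or float64); vendor extensions are out of scope, and there is no HDF5
  reader.
* The CARS column-permutation invariance holds in distribution, not
  draw-for-draw: weighted sampling consumes the RNG stream in column
  order, so a permuted block with the same seed can select a different
  (equally valid) run; recovery of informative variables is what the
  tests assert.
* The decision-fusion weights and all report values on synthetic data
  are not estimates of any real shrimp experiment's numbers; only the
  qualitative structure (spectra dominant, fusion at least as good as
  single blocks in calibration) is expected to transfer.
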