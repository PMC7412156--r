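---
title: "Dynamic infrared thermography screening: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic infrared thermography screening: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoseries)
```

## The screening problem

Dynamic infrared thermography (DIT) records a sequence of thermograms while
the breast re-warms after an induced cooling stimulus (typically an electric
fan for a few minutes). Tumor-bearing tissue is hyper-vascularised and
metabolically active: it sits slightly warmer at baseline and, crucially, is
barely affected by the cooling, while healthy tissue cools several degrees
and recovers toward baseline over minutes. A 20-frame exam sampled every
15 s (about 0.066 images/s over 5 minutes) therefore carries a *temporal*
signature of disease that a single static thermogram does not.

`thermoseries` turns that signature into a classification: each breast's
frame sequence becomes a set of feature *trajectories*, the trajectories are
decimated into coarser sub-series, each sub-series is summarised by two
scalars, and a support vector machine separates healthy from sick breasts
under leave-one-out cross-validation (LOOCV).

## The pipeline

1. **Temperature arrays.** Each frame is a plain-text grid of skin
   temperatures in °C (nominally 640×480). Masks delimiting the breast
   (the ROI) accompany every frame; all computation happens inside the ROI.
2. **Shared gray scale.** Image-texture features need an 8-bit image. Every
   frame in the study is quantized with the *same* affine map
   `g = 255 (T - min) / (max - min)`, where `min`/`max` are the global
   extrema over all frames of the cohort, so gray levels are comparable
   across frames and breasts.
3. **Phase-1 features.** Per frame (or per consecutive frame pair), 26
   scalar features are computed inside the ROI (next section), giving 20-
   or 19-point trajectories per breast.
4. **Sub-series.** Each trajectory is decimated à la Higuchi:
   `x(m), x(m+k), x(m+2k), ...` for `k = 1..4`, `m = 0..k-1` — ten
   configurations in all, whose index sets partition the original series.
5. **Phase-2 features.** Each sub-series collapses to two scalars: its
   root mean square (`R` columns) and its amplitude max−min (`A` columns).
6. **Selection and classification.** Correlation-based feature selection
   (CFS) with best-first search picks a small subset; features are min-max
   normalized to [0, 1]; an RBF-kernel SVM (C-SVC or Nu-SVC) is evaluated
   by LOOCV, reporting sensitivity, specificity, accuracy and Youden's
   index from the aggregated confusion table.

The recommended operating point is `k = 4, m = 0` with C-SVC: sub-series
built from only 5 of the 20 frames, which both denoises the trajectories
and minimises the computation needed at exam time.

## Phase-1 features

**Simple statistics** — ROI mean temperature and standard deviation. The
standard deviation is the population form (divide by *n*): the ROI is the
entire population of pixels, not a sample, and fixing the form makes tests
bit-exact.

**Grouping** — the hottest of 9 centroids from 1-D k-means over the ROI
temperatures, with k-means++ seeding and convergence when the total
within-group sum of squared residuals changes by less than 0.01 (cap 1000
iterations). The hottest centroid tracks the warm plateau a tumor maintains
through the recovery. Clustering is on temperatures only — no spatial
coordinates — so it is invariant to any permutation of ROI pixels.

**Histogram distances** — Bhattacharyya, chi-square and intersection
distances between the 256-bin gray histograms of consecutive frames
(19 values per breast). Histograms are normalized first; the chi-square sum
skips bins where the reference probability is zero. All 256 bins are always
used, whether or not a level occurs in the ROI.

**Unser textures** — sum and difference histograms over horizontally
(`Dx=1, Dy=0`) and vertically (`Dx=0, Dy=1`) displaced pixel pairs, *both*
members inside the ROI, give six texture estimators each: energy, entropy
(natural log), contrast, variance, correlation, homogeneity. For a constant
image the correlation estimator is defined as 0 (both of its terms vanish).

**Diversity indices** — the same sum/difference histograms, segmented into
consecutive groups of 7 bins (511 = 7·73, so 73 + 73 = 146 "species"),
yield McIntosh, Simpson (dominance form) and Berger-Parker indices per
neighborhood: measures of how concentrated the pair mass is.

**Spatiogram** — a histogram whose bins also carry the spatial mean and
covariance of their pixels. Consecutive frames are compared with the
second-order similarity `rho = sum_b psi_b sqrt(p_b q_b)`, `psi_b` the
normalized Gaussian similarity of the bin moments, calibrated so identical
spatiograms score exactly 1. Bin covariances are regularized by `eps I`
with `eps = 0.25` px² so singleton and collinear bins have proper
densities. Frames are assumed spatially registered — true by construction
for the synthetic generator; clinical sequences must be registered upstream.

**Lacunarity** — gliding-box gray-scale lacunarity
`Lambda(r) = N_B sum(M²) / (sum M)²` with box masses `M` the sum of gray
values (out-of-ROI pixels count zero), stride 1 inside the ROI bounding
box, box sizes 2, 4, 8, 16, 32, 64. Sizes larger than the bounding box are
skipped; the feature is the arithmetic mean of `Lambda(r)` over the valid
sizes (the mean is the natural single-number reduction and keeps the
constant-image value at exactly 1).

## Phase-2 features and naming

For a sub-series `x` of length `n`: `M2 = sqrt(sum(x²)/n)` (root mean
square — overall magnitude) and `R = max(x) − min(x)` (amplitude — how far
the feature travels during recovery). Column names follow the screening
literature's reporting convention: the `"R "` prefix denotes the root of
the second moment (M2) and `"A "` the amplitude. Pairwise-feature
trajectories have 19 points rather than 20; their sub-series are formed by
the same index rule without padding (so at `k = 4` they have 5 or 4
elements depending on `m`).

The Higuchi normalized curve length
`L(m,k) = sum |x(m+ik) − x(m+(i−1)k)| · (N−1)/(I k) / k` is provided for
completeness (`higuchi_length()`) but feeds nothing downstream. Under
0-based indexing the in-range cap is `I = floor((N−1−m)/k)`, which is also
used in the normalization factor; this is the one place where the standard
printed form of the formula (with `floor((N−m)/k)`) would address an
out-of-range element.

## Selection, normalization and the leakage question

CFS scores a subset of `s` features as
`merit = s·r̄_cf / sqrt(s + s(s−1)·r̄_ff)` — high mean feature–class
correlation `r̄_cf`, low mean feature–feature correlation `r̄_ff`
(absolute Pearson correlations; zero-variance features contribute 0).
Best-first forward search expands the highest-merit subset on an open
list, stopping after 5 consecutive non-improving expansions; ties break by
column order so selection is deterministic.

By default, both the normalization bounds and the selected subset are
fitted once on the full matrix *before* the LOOCV loop. That protocol is
what makes a single per-configuration feature subset reportable, and it is
the default here for comparability; it is, however, optimistically biased,
because the held-out breast influenced the selection. `fold_safe = TRUE`
refits bounds and subset inside every fold — the honest generalization
estimate — at the cost of a possibly different subset per fold. Both modes
are first-class; the choice is explicit in every report.

SVM defaults mirror the standard libsvm tooling: `C = 1`, `nu = 0.5`,
`gamma = 1/n_features`, RBF kernel, termination tolerance `1e-3`. Sick is
the positive class. Because discrete LOOCV predictions admit no threshold
sweep, the report carries two "areas": the balanced accuracy
`(sens+spec)/2` labelled `auc_balanced`, and `roc_acc_scale = acc/100`,
the accuracy restated on the unit scale as screening tables sometimes
print it. Neither is a true ROC integral.

## The synthetic exam generator

Without clinical data the pipeline is exercised on synthetic cohorts that
reproduce the physiology the method exploits, per pixel and frame:

```
T(x, y, t) = T0 + delta·[tumor] − dT_eff·exp(−t·dt/tau) + N(0, sigma²)
```

with `dT_eff = delta_T` outside the tumor disk and `delta_T (1 − rho)`
inside it. Defaults, chosen once as a plausible post-cooling physiology:
baseline `T0 = 33` °C (per-breast jitter ±0.5 °C), cooling drop
`delta_T = 3` °C, recovery constant `tau = 180` s against the 300 s exam
(so recovery is clearly underway but incomplete — the regime in which DIT
is informative), tumor elevation `delta = 1.5` °C with recovery
suppression `rho = 0.9`, camera noise `sigma = 0.03` °C (the emulated
camera's thermal sensitivity is below 0.04 °C), 20 frames 15 s apart. The
ROI is a half-ellipse breast silhouette, identical in every frame, so
sequences are registered by construction. Default frame size is 160×120 —
the full 640×480 clinical format is available by configuration, and all
features are resolution-robust ratios or per-pixel statistics, but the
reduced size keeps a 64-breast study tractable on a laptop-class machine
(about a minute of feature extraction; the test-suite constructions use
64×48 or smaller for the same reason).

What the generator does *not* emulate: vascular structure, spatially
correlated (Pennes-type) heat diffusion, breast-shape variation,
registration error, or segmentation noise. Passing the end-to-end tests
therefore shows the machinery recovers a *thermal-recovery* class signal
under camera noise; it says nothing about performance on clinical images,
where texture features carry structure this generator cannot produce.

With the default effect the 32+32 design is cleanly separable (LOOCV
accuracy ≥ 95%); with `delta = 0, rho = 0` the classes are exchangeable
and accuracy falls inside the binomial 95% interval around chance. Note
one statistical subtlety of balanced-noise LOOCV: the held-out breast's
class is always the training minority, which biases null accuracy *below*
50% when many noise features feed the SVM; with CFS selection ahead of the
loop (upward-biased on noise) the two effects roughly cancel at this
design size.

## Numerical choices and degenerate inputs

- Gray quantization rounds to the nearest integer, half away from zero
  (whether the original tooling rounded or truncated is unstated; nearest
  minimises quantization bias, and fixing it makes tests bit-exact).
  Temperatures outside the fitted extrema clip to 0/255 at prediction time.
- A cohort whose frames are all one temperature has no gray scale
  (`max == min`) and is rejected rather than silently mapped.
- Constant columns normalize to 0; out-of-range values clip to [0, 1].
- k-means clusters that empty keep their previous centroid; an all-equal
  ROI converges immediately to that value.
- Chi-square skips zero-probability reference bins; McIntosh is defined as
  0 when `N = 1` (its denominator vanishes).
- Empty masks, ragged grids, non-numeric tokens, dimension mismatches and
  duplicate breast ids are hard errors with the offending file or line
  named; temperatures outside 15–45 °C warn but load.
- All randomness (k-means++ draws, synthetic noise, per-breast jitter) is
  seed-controlled; derived seeds stay below 2³¹.

## Problem sizes used in the shipped checks

The package's own verification uses: oracle comparisons on ≤ 32×32 random
images (brute-force double loops recomputed live); a 64-breast, 1280-frame
cohort at 4×4 resolution for manifest-scale IO; end-to-end class-recovery
runs on 32+32 breasts at the default 160×120 resolution; and smaller
64×48 cohorts for pipeline-routing tests. These sizes were chosen so the
full suite exercises every stage at realistic scale while remaining
desk-runnable.

## Known limitations

- The texture families (Unser, diversity, lacunarity, spatiogram) are
  validated against oracles and invariants, but their discriminative value
  is only demonstrated on synthetic recovery physiology.
- No image registration is provided beyond the generator's by-construction
  alignment; spatiogram comparison of unregistered clinical frames will
  under-read similarity.
- The default (non-`fold_safe`) protocol overstates generalization for the
  reasons above; treat its numbers as comparable-to-literature, not as
  honest out-of-sample estimates.
- Proprietary radiometric formats are out of scope: temperature grids must
  already be exported as text.
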