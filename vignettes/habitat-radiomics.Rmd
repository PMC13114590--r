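---
title: "Habitat radiomics for pleural-invasion prediction: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics for pleural-invasion prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Visceral pleural invasion (VPI) upstages a lung adenocarcinoma to T2
regardless of size, so a preoperative, noninvasive call on VPI status in
subpleural nodules changes surgical planning. Conventional predictors are
radiological measurements — solid-component diameter, consolidation-to-tumor
ratio (CTR = 100 × solid diameter / maximal diameter), lesion– and
solid–pleural contact lengths (PL, SPL), lesion–pleura distance (DLP) — and
whole-lesion radiomic texture. Habitat analysis adds a spatial axis: each
lesion is partitioned into subregions of coherent intensity statistics
("habitats"), and texture is quantified per habitat, so that signal confined
to one subregion (an invasive peripheral rim, a busy tumor–pleura transition
zone) survives instead of being averaged away.

All three models in this package are logistic signatures
ln[p/(1−p)] = β₀ + Σ βᵢ xᵢ with a probability cutoff; the positive class
requires p strictly greater than the cutoff. They differ only in their
feature space: raw millimetre measurements (radiological), 106 whole-lesion
radiomic features (radiomic), or 279 per-habitat features (habitat).

## Pipeline stages and their parameters

**Preprocessing.** Volumes are resampled to `target_spacing` (default
1×1×1 mm, trilinear; masks nearest-neighbor), clipped to the lung window
(default −1250 to 250 HU, i.e. width 1500 / level −500), and z-normalized
to mean 0, variance 1 within the lesion mask. We use the population (÷n)
variance so the post-condition is exactly testable. Normalization is
per-lesion, not per-volume: the clustering statistics should describe the
lesion's internal contrast, not the surrounding parenchyma. Gray-level
discretization for texture uses a fixed *count* of 25 equal-width bins over
the masked intensity range (not a fixed bin width); intervals are half-open
with the top edge closed, so the masked maximum falls in bin 25 and a
constant lesion occupies bin 1. Fixed-bin-count makes texture features
invariant to affine intensity transforms, which is the behavior the
harmonization audit assumes.

**Superpixels.** `slic3d()` runs spacing-aware SLIC on the z-normalized
intensities restricted to the mask: joint distance
d² = d_intensity² + compactness²·(d_spatial/S)², with S the expected
superpixel radius for the requested count (default 50 per lesion) and
compactness 0.1 — low enough that superpixels follow intensity boundaries,
which matters because habitats are intensity phenotypes. After assignment,
disconnected fragments are merged into adjacent superpixels by growing a
frontier from each label's dominant component, so every final superpixel is
26-connected. Masks smaller than the requested count degrade to one
superpixel per voxel with a warning.

**Habitat clustering.** Ten first-order statistics per superpixel (mean,
median, population variance, skewness, excess kurtosis, min, max, 10th/90th
percentiles, 25-bin histogram entropy; single-voxel superpixels get
variance/skewness/kurtosis 0 by convention) are pooled over training
lesions, z-scored with training statistics, and clustered by K-means
(k-means++ seeding, 10 restarts, Lloyd iterations, fixed seed). The fitted
standardization and centroids are frozen: validation and test lesions are
assigned to the nearest training centroid, never re-fit, and habitat
identity is the centroid index. `select_k()` returns the Davies–Bouldin
argmin over K = 2..10 (ties to the smallest K). On the published DB curve
the argmin falls at K = 4 while the published choice is K = 3; we keep
`select_k()` faithful to the minimum and expose the working K as an explicit
configuration default (`run_config(K = 3)`), so both behaviors are
available and neither is silently guessed.

**Feature catalog.** Whole-lesion extraction emits exactly 106 features.
The five texture families follow the IBSI formulations: GLCM (symmetric,
13 unique 3D directions at distance 1, features averaged over directions),
GLRLM (same directions), GLSZM (26-connected iso-intensity zones), GLDM
(α = 0, distance 1, 26-connectivity), NGTDM (26-neighborhood means,
degenerate denominators → 0, Coarseness → 10⁶). The usual 24-feature
co-occurrence set is reduced to 23 by excluding SumAverage, which under
matrix symmetry is exactly twice JointAverage; this makes the 106-count
contract explicit rather than accidental. Per-habitat extraction keeps all
non-shape families plus `shape_VoxelVolume` (93 per habitat; 279 for
K = 3) and re-discretizes within each habitat mask, so per-habitat texture
describes the habitat's own gray-level structure. A habitat absent from a
lesion produces an all-missing 93-feature block.

**Missing habitats.** Absent blocks are imputed missForest-style: columns
initialized at observed means, then each column with missingness refit by a
random forest on all other columns, sweeping until the relative change in
imputed values rises or `max_iter` is reached; the diverging sweep is
rolled back. Validation/test rows are imputed with the completed training
rows appended as reference data, so no labels and no validation statistics
leak into training. The count of imputed case×habitat blocks is reported
per split.

**Harmonization.** Feature-level (not voxel-level) batch adjustment with
the parametric empirical-Bayes location–scale model: features are
standardized against a batch-size-weighted grand mean and pooled variance;
per-batch location/scale estimates are shrunk toward normal /
inverse-gamma priors; the fitted parameters are frozen and reusable on new
cohorts (batches unseen at fit time are an error). The biological label is
*not* a protected covariate by default but can be supplied. The audit
reports the mean per-feature one-way-ANOVA R² of batch before and after,
the relative reduction, and a paired t-test over features. Our
implementation matches the reference empirical-Bayes implementation to
4 decimals on shared fixtures (see the test suite).

**Selection chain and signatures.** On z-scored training features (frozen
means/sds stored in the model): (1) Spearman pruning removes one member of
every pair with |ρ| > 0.9, keeping the member with the smaller univariate
Mann–Whitney p; (2) the Mann–Whitney screen keeps two-sided p < 0.05 (on
very small cohorts that can empty the set, in which case the strongest
candidates continue with a warning); (3) mRMR retains the top 10 under the
mutual-information-difference objective, with MI estimated on
equal-frequency 4-bin discretizations; (4) LASSO (10-fold stratified CV,
penalty at minimum deviance, seeded folds) keeps nonzero coefficients.
Backward elimination then drops the largest Wald p until all p < 0.05. The
classification cutoff is the Youden point on training probabilities (ties
to the lower cutoff); the published cutoffs are shipped verbatim in the
reference models. If the unpenalized fit separates perfectly — a small-n
phenomenon, not a real-data concern at the published cohort sizes — the
penalized fit itself is kept as the signature, since its coefficients are
finite by construction. The radiological path mirrors the published
procedure: univariate logistic screen at p < 0.05, then backward
elimination on the raw-scale measurements.

**Evaluation.** AUC uses the midrank Mann–Whitney formulation; its CI uses
the DeLong variance on the logit scale so bounds respect [0, 1]. The paired
DeLong test uses structural components; degenerate pairs (identical
predictors) are an error at the operation level and an NA row in the
pipeline's pairwise table. Confusion metrics are exact count fractions with
one-decimal percent rounding, matching the printed convention
("64/73 [87.7%]"). Calibration uses 10 equal-width probability bins (empty
bins omitted); decision curves use NB(t) = TP/n − FP/n·t/(1−t) on a
0.01–0.80 grid. Inter-rater agreement is ICC(2,1) — two-way random
effects, absolute agreement, single measurement; the form is stated
explicitly because different ICC forms differ materially.

## The phantom generator

`generate_cohort()` draws, per case: maximal diameter (log-normal around
19.5 mm, truncated to 10–28 mm, respecting the < 30 mm inclusion rule),
part-solid composition with probability 0.6 (solid otherwise, with
solid diameter = CTR × maximal diameter, CTR ~ U(0.3, 0.95) for part-solid
cases), pleural attachment with probability 0.55 (detached cases sit
0.5–6 mm from an axis-aligned pleural plane), and a lobulated spherical
lesion whose solid component sits tangent to the pleural side. Contact
lengths have closed forms from the clipped-sphere geometry (PL and SPL as
chords at the plane), which the mask-based measurement operation recovers
on the voxel grid.

Subregion ground truth covers every lesion voxel: for part-solid cases the
core is the solid component and the ground-glass shell splits into a
transition zone and a peripheral rim; solid nodules carry a thin
partial-volume rim and transition band at the lung interface, as real solid
nodules do on CT — this keeps the cohort's missing-habitat rate low and of
the same order as published per-split imputation rates rather than making
40% of cases single-habitat. Mean HU defaults are −600 (rim), −300
(transition), +20 (core), with lung parenchyma at −850 and chest wall
below the plane at +20.

Subregion-level texture is a speckle process: a per-case fraction of rim
voxels (U(0.1, 0.5)) receives a +150 HU component. The fraction is the
latent rim-texture covariate of the label model. The transition zone
receives an independent nuisance speckle of the same form, so whole-lesion
histogram statistics see a mixture of the two sources while only a
spatially resolved analysis isolates the rim component — this is the
designed sense in which the cohorts carry subregion-level signal. A
speckle (fixed-amplitude bimodality) rather than Gaussian noise-level
modulation is essential: fixed-bin-count discretization over a region's own
intensity range normalizes away pure scale changes, so a noise-sd covariate
would be invisible to every discretized texture family; a mixture fraction
changes histogram *shape* and drives exactly the busyness / skewness /
gray-level-emphasis features the habitat signature uses.

Batch structure: five scanner batches assigned round-robin, each with a
multiplicative HU scale (0.95–1.05), then an additive shift (−25 to
+25 HU), then Gaussian noise (sd 35–45 HU), applied before clamping to
[−1024, 400] HU. The VPI label is Bernoulli with logit
β₀ + 1.2·z(solid diameter) + 0.9·z(SPL) + 0.7·z(rim texture), the
covariates standardized within the cohort so coefficients are scale-free;
β₀ is solved so the realized mean probability equals the configured
prevalence (default 0.38, the training-set prevalence scale of the study
design this emulates). Effect-size defaults put geometry first and texture
second, mirroring the strong group differences in solid diameter and SPL.

What the phantom deliberately does **not** model: CT physics (beam
hardening, reconstruction kernels, partial volume beyond the rim band),
semantic signs (lobulation and spiculation appear only as boundary
perturbation; they carry no label signal, consistent with their reported
non-significance), respiratory/cardiac motion, and annotation error in
masks. Consequently, passing tests demonstrate that the pipeline's
machinery is correct and that it recovers planted subregional signal under
scanner heterogeneity — not that any particular clinical AUC is
reproducible.

## Problem sizes used by the tests

The test suite and acceptance script run end-to-end cohorts at n = 60 with
the default geometry and two identically-seeded repetitions for the
determinism check; the habitat-versus-whole-lesion ordering property uses
20 cohorts of n = 40 with the label weighted toward the rim-texture
covariate (coefficients 0.6 / 0.4 / 1.2), which is the configuration that
realizes "cohorts constructed with subregion-level signal"; statistical
calibration checks use 2000 DeLong null replicates at n = 150 and
parameter-level cohorts of n = 200–1000 (the generator's parameter stage is
separable from volume synthesis precisely so calibration studies do not pay
for image generation). These sizes are the package's chosen desk-scale
study conditions; the pipeline itself has no dependence on them.

## Known limitations

- Subregion recovery has a resolution floor: near-solid lesions
  (CTR ≳ 0.7) carry ground-glass shells thinner than a superpixel, and
  strong intra-subregion speckle migrates superpixels across intensity
  clusters, so habitat maps match the constructed subregions well only
  where the subregions exist at superpixel scale (the generator's
  `ctr_range` lets studies control this). This mirrors the habitat
  reassignment effect expected under noisy acquisition.
- Habitat identity is the frozen centroid index; centroid numbering is
  arbitrary across *different* training runs, so models from different
  seeds must not be mixed (serialize and reload instead).
- The habitat model integrates the selected per-habitat features in a
  single logistic equation (the published reference form); a stacking
  variant that combines per-habitat probabilities is not implemented.
- Mesh-based shape quantities (surface area, volume) are voxel-face
  approximations, adequate for the catalog contract and phantom scale but
  coarser than marching-cubes implementations.
- JSON model serialization carries 15–17 significant digits; round-trip
  predictions agree to ~1e-12 relative, and classes are bit-stable.
- With ≤ 20-case cohorts the selection chain's small-sample fallbacks
  (screen fallback, penalized-fit signature) engage; published-scale
  cohorts (hundreds of cases) never hit them.
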