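# habitomics

Habitat-based radiomics for predicting visceral pleural invasion (VPI) in
subpleural lung nodules on low-dose CT, as a tested, reusable R pipeline.

Subpleural adenocarcinoma nodules that invade the visceral pleura (a T2
staging criterion) are hard to call preoperatively. Whole-lesion radiomic
models treat the tumor as homogeneous; habitat analysis instead partitions
each lesion into subregions ("habitats") by unsupervised clustering and
extracts texture features per habitat, so that spatially localized signal —
an invasive rim phenotype, a busy tumor–pleura transition zone, a necrotic
core — is not washed out by whole-lesion averaging.

Patient imaging for this problem is not publicly distributable, so the
package ships a synthetic nodule phantom generator that reproduces the
structure the analysis relies on: subpleural nodules abutting a planar
pleura, three latent intensity subregions (rim / transition / core),
part-solid and solid composition, per-scanner batch effects, and a VPI label
drawn from a logistic model on solid-component diameter, solid–pleural
contact length (SPL) and rim texture. Every stage of the pipeline is
exercised end-to-end on these phantoms with no external data.

## The pipeline

1. **Preprocessing** — resampling to 1×1×1 mm voxels (trilinear), clipping
   to the lung window (−1250 to 250 HU), per-lesion z-normalization, and
   fixed-bin-count discretization into 25 gray levels.
2. **Habitats** — 3D SLIC partitions each lesion into ≤50 spatially
   connected superpixels; 10 first-order statistics per superpixel feed a
   K-means model (fit on the training split only, then frozen); the
   Davies–Bouldin index guides the choice of K; missing habitat feature
   blocks are imputed by iterative random forests.
3. **Features** — an IBSI-style catalog: 106 whole-lesion features (14
   shape, 18 first-order, 23 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM)
   and 93 features per habitat (all non-shape families plus voxel volume),
   i.e. 279 for K = 3.
4. **Harmonization** — parametric empirical-Bayes location–scale batch
   adjustment of the feature table across scanner batches, fit on training
   and applied frozen to validation/test, with a batch-R² audit.
5. **Signatures** — a four-step selection chain (Spearman |ρ|>0.9 prune,
   Mann–Whitney screen, mRMR top-10, LASSO at the CV-minimum penalty)
   followed by backward-elimination logistic regression:

   ln[p/(1−p)] = β₀ + Σ βᵢ xᵢ,  class = [p > cutoff]

   fitted in parallel as a radiological signature (raw measurements), a
   whole-lesion radiomic signature and a habitat signature.
6. **Evaluation** — ROC/AUC with DeLong confidence intervals and paired
   DeLong tests, sensitivity/specificity/PPV/NPV in printed-fraction form,
   Brier scores, calibration curves, decision-curve analysis, and ICC(2,1)
   inter-rater agreement.

The published model equations are shipped as reference `signature_model`
objects (`reference_signatures()`), e.g. the habitat signature
ln[p/(1−p)] = −1.032 − 0.706·Habitat1_firstorder_Skewness + 0.504·Habitat1_GLDM_SmallDependenceEmphasis − 1.234·Habitat2_NGTDM_Busyness − 0.826·Habitat3_GLCM_ClusterProminence − 0.712·Habitat3_NGTDM_Contrast,
with VPI called positive when p > 0.476.

## Worked example

```r
library(habitomics)

res <- run_pipeline(run_config(
  cohort = cohort_config(n_cases = 60, seed = 1),
  seed = 1))
res
#> habitat radiomics pipeline result
#> -- train --
#>         model       auc sensitivity_pct specificity_pct  brier
#>  radiological 0.7931            ...             ...      0.178
#>      radiomic 0.7878            ...             ...      0.171
#>       habitat 0.8939            ...             ...      0.131
res$audit
#> batch R2 audit: mean 7.53% -> 3.11% (relative reduction 58.7%), paired p < 0.001
```

On this synthetic cohort the habitat signature reaches a training AUC of
0.894 against 0.788 for the whole-lesion radiomic signature and 0.793 for
the radiological signature, and batch harmonization removes 58.7% of the
mean per-feature variance explained by scanner batch. The absolute AUCs are
properties of the phantom cohort, not estimates of clinical performance.

Individual stages are exported and composable:

```r
co   <- generate_cohort(cohort_config(n_cases = 20, seed = 7))
case <- co$cases[[1]]
vol  <- clip_window(case$volume, preproc_spec())
voln <- znormalize(vol, case$lesion_mask)
sp   <- slic3d(voln, case$lesion_mask, n_superpixels = 50)
feats <- extract_whole(vol, case$lesion_mask)   # 106 named features
```

## Vignette

`vignettes/habitat-radiomics.Rmd` documents the model and its assumptions,
the phantom generator's design (what it emulates and what it deliberately
does not), every tunable parameter with its default and rationale, and the
numerical conventions (binning, tie-breaks, degenerate inputs).
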