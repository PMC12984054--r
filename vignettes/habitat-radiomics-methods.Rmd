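---
title: "Methods: habitat and peritumoral CT radiomics for STAS prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat and peritumoral CT radiomics for STAS prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(habstas)
```

## The problem

Spread through air spaces (STAS) — micropapillary clusters, solid nests or
single tumor cells occupying airspaces beyond the edge of the main tumor —
is a pathological invasion pattern that can only be confirmed after
resection, yet it bears directly on the preoperative choice between
segmentectomy and lobectomy for small (≤ 2 cm) solid lung adenocarcinomas.
`habstas` implements a complete, testable CT pipeline for preoperative STAS
prediction that combines three information sources:

1. **Intratumoral habitats** — the tumor is partitioned into subregions with
   distinct local-texture statistics by per-patient K-means on voxel-level
   feature vectors, and radiomic features are extracted per habitat;
2. **Peritumoral rings** — shells at 1, 3 and 5 mm outside the tumor
   boundary, where STAS lesions physically reside;
3. **Clinical/CT covariates** — including the mediastinal-window tumor
   size, the usual independent clinical predictor of STAS in this setting.

Region models are trained per feature block, and the habitat, 3 mm
peritumoral and clinical models are fused by probability stacking into a
combined model.

Because no patient CT archive accompanies this implementation, every stage
is validated against a synthetic phantom cohort with *known* habitat
structure, peritumoral signal and label-generating model.

## Pipeline stages and their parameters

### Preprocessing

CT volumes are resampled to isotropic 1 mm voxels with an interpolating
cubic B-spline (recursive prefilter with pole √3 − 2, then separable cubic
basis evaluation; masks use nearest-neighbour interpolation so no new labels
appear). Intensities are then normalised with the lung display window
(width 1500 HU, level −500 HU), mapping [−1250, 250] HU linearly onto
[0, 1]. Windowing is applied after resampling; out-of-field voxels created
by resampling are filled with −1024 HU (air). Radiomic features are computed
on the windowed intensities — the windowed scale is the one the rest of the
pipeline sees, and fixed 32-bin discretisation on [0, 1] is stable across
patients (a sensitivity point worth revisiting on real data, where raw-HU
extraction is also defensible).

### Peritumoral rings

Rings are exact Euclidean-metric dilations: a voxel belongs to the
`d`-ring iff its centre lies within `d` mm of some tumor voxel centre,
honouring anisotropic spacing, minus the tumor, intersected with the lung
mask. The lung-mask intersection replaces the manual chest-wall/mediastinum
correction of interactive workflows: it is reproducible and is exercised in
the phantom by a chest-wall slab abutting the lung. For real data without a
lung mask, `lung_mask_from_hu()` supplies a HU-threshold heuristic
(< −300 HU). Rings are strictly exterior to the tumor; intratumoral
cavities are not added to rings.

### Habitat clustering

Every tumor voxel gets a 19-statistic local feature vector from the 5×5×5
moving window centred on it: mean, median, min, max, range, variance, SD,
skewness, kurtosis, energy, RMS, entropy (32 fixed bins on [0, 1]),
uniformity, MAD, robust MAD, and percentiles 10/25/75/90. The window is
clipped at volume borders (never padded) and, by default, restricted to
voxels inside the tumor mask. The restriction matters: without it, the
~500 HU attenuation jump from tumor to aerated lung dominates every
within-tumor texture contrast, and clustering degenerates into an
interior-versus-boundary split for any planted structure — with it, habitat
structure reflects intratumoral texture, which is what habitat imaging is
after. The unmasked behaviour remains available (`mask_windows = FALSE`).

Features are Z-scored within each sample; K-means (k-means++ seeding, 10
restarts, fixed seed) partitions the voxels; clusters are relabelled in
increasing order of mean windowed intensity so that "habitat 1" is the
darkest subregion in every patient — a deterministic, interpretable
cross-patient correspondence rule for a problem the clustering itself does
not solve. The habitat count is selected once, cohort-wide, as the k in
2..8 maximising the *mean per-sample* Calinski–Harabasz index (per-sample k
is deliberately not allowed; a cohort-level k keeps feature blocks
comparable across patients). Whether voxel features should be Z-scored
before K-means, and whether CH should be averaged or pooled across patients,
are genuinely open choices; the package Z-scores (the 19 statistics live on
wildly different scales) and averages (so large tumors do not dominate).

### Feature extraction

Each region (intratumoral, peri1/3/5, each habitat) yields 88 features on
the original image: 14 shape, 18 first-order, 24 GLCM, 16 GLRLM and
16 GLSZM, following the standard reference formulas. Specifics worth noting:

- surface area and mesh volume come from a marching-tetrahedra
  triangulation of the lightly smoothed binary indicator at iso-level 0.5
  (the smoothing recovers sub-voxel boundary position; a digital ball of
  radius 8 measures within ~0.1% of its analytic area);
- GLCM is symmetric, distance 1, averaged over the 13 unique 3-D
  directions; discretisation is fixed-bin-count 32 over the region's
  intensity range;
- GLSZM zones are 26-connected components of equal discretised gray level.

Filtered-image (wavelet/LoG) variants — which commercial platforms add to
reach feature counts in the thousands — are intentionally out of scope; the
88 original-image features are the documented, testable core.

A habitat subregion can be absent or tiny in a patient (clustering is
unsupervised); such blocks become missing cells and are filled by KNN
imputation: the mean of the 5 nearest *training* rows by Euclidean distance
on Z-scored fully observed columns. The imputation model is fitted on the
training split only and applied to all splits.

### Feature selection cascade

Stages, in order, all fitted on training rows only; survivors are nested:

1. **ICC filter** (when repeat-delineation ratings exist): ICC(2,1) —
   two-way random effects, absolute agreement, single rater — keeps
   features with ICC > 0.75 in both the inter- and intra-observer designs.
   Synthetic cohorts have a single deterministic "reader", so pipeline runs
   skip this stage; it is exercised directly in the test suite.
2. **Z-score** normalisation (train-fitted scaler, applied everywhere;
   zero-variance training columns dropped).
3. **Mann–Whitney U screen** at two-sided p < 0.05.
4. **Pearson redundancy pruning** at |r| > 0.9, visiting pairs in
   decreasing |r| and dropping the member with the larger U-test p (ties:
   the lexicographically later name).
5. **mRMR** with the MID criterion (relevance minus mean redundancy),
   plug-in mutual information after equal-frequency 4-bin discretisation,
   default m = 30.
6. **LASSO** logistic regression, 100-value log-spaced λ path, stratified
   10-fold CV; λ* minimises mean CV binomial deviance (the 1-SE rule is
   available as `rule = "1se"` — more specific, slightly less sensitive).
   If λ* zeroes everything, the knee (largest λ with one nonzero
   coefficient) is used and logged.

### Models and fusion

Five families — logistic regression, KNN, random forest, gradient-boosted
trees, and a single-hidden-layer perceptron — are each tuned by stratified
5-fold CV on the training split over small fixed grids (trees ∈ {100, 300},
depth ∈ {6, unlimited}; boosting rounds ∈ {50, 150}, depth ∈ {3, 6};
k ∈ {3, 5, 7, 11}; hidden units ∈ {4, 16}, weight decay ∈ {1e-3, 0.1}) —
reproducibility is preferred over grid exhaustiveness. The winner per
region is the algorithm with the highest *validation-split* AUC; validation
labels influence nothing else, and the test split influences nothing at
all. (Winner selection on the validation split biases reported validation
AUCs upward; the untouched test split is the honest yardstick.) The binary
operating threshold is Youden-optimal on the training split and frozen.

The combined model stacks habitat, 3 mm peritumoral and clinical
probabilities: out-of-fold (stratified 5-fold) base probabilities on the
training split form a 3-column design for an unpenalised logistic
meta-learner. Out-of-fold is essential — in-fold probabilities of flexible
bases (a 1-NN memorises its training labels) would hand the meta-learner a
leaked outcome. Simple probability averaging is available as
`method = "average"`.

### Evaluation

AUC with DeLong structural-component variance and normal 95% CI; paired
DeLong tests between models; accuracy/sensitivity/specificity/PPV/NPV at
the frozen threshold; Hosmer–Lemeshow calibration over deciles of risk
(`fitted_df = 2` classical correction for in-sample fitted probabilities;
`fitted_df = 0` is the calibrated reference for exogenous probabilities —
the package exposes both because the classical correction is
anticonservative or conservative depending on provenance of the
probabilities); decision curves with net benefit
`TP/n − (FP/n)·pt/(1−pt)` over thresholds 0–0.99; Wald odds ratios with
Haldane correction for zero cells; univariable/multivariable logistic
regression with a Jeffreys-penalised fallback under separation; Cohen's
kappa. No multiplicity correction is applied anywhere (matching the p<0.05
univariable gate convention of the clinical literature this pipeline
follows).

## The phantom cohort

`phantom_config()` / `generate_cohort()` define the study conditions:

- **Anatomy.** 64³ voxel volumes at 1 mm isotropic spacing; parenchyma
  N(−800, 30²) HU; an optional +40 ± 10 HU chest-wall slab on one face
  (excluded from the lung mask); one solid ellipsoidal tumor per patient
  with maximum diameter uniform on (10, 20] mm. The lower bound keeps all
  three planted subregions resolvable; the upper bound is the ≤ 2 cm
  inclusion criterion.
- **Habitats.** `k_true = 3` subregions arranged as *angular sectors*
  around the tumor centre with random widths (volume-fraction floor so no
  sector degenerates), random orientation, and wavy boundaries. Sectors —
  not concentric shells — because at these tumor sizes a shell is 1.5–3
  voxels thick, thinner than the 5³ feature window, and would be smoothed
  into an unrecoverable radial continuum; sectors give every subregion bulk
  interior volume. Subregion HU laws (mean, SD, texture correlation
  length): (60, 15, 1), (10, 25, 2), (−80, 40, 3) core→outward; texture is
  Gaussian noise smoothed at the stated correlation length and rescaled to
  the stated SD.
- **Peritumoral signal.** A latent per-patient texture score adds noise of
  SD `25·exp(0.5·score)` HU to the 3 mm shell; the score correlates 0.5
  with the (standardised) subregion-3 fraction — one tumor biology drives
  both intratumoral composition and peritumoral spread.
- **Clinical table.** Marginals match the published training-cohort
  distributions (sex ~48% male, smoking 28%, CEA+ 17%, SCCA+ 2%, NSE+ 34%,
  CYFRA+ 20%, lobulation 90%, spiculation 32%, bronchial cut-off 16%, air
  bronchogram 40%, vacuole 30%; age N(62.8, 8.1); lung-window size = true
  diameter + noise; mediastinal-window size = diameter × U(0.6, 0.95) +
  noise).
- **Label model.** `P(STAS) = expit(−1.15 + 1.2·z(Mwts) + 2.2·z(frac₃) +
  1.3·z(peri))` on cohort-standardised covariates. The coefficients were
  calibrated by direct simulation of this model so that the *true*
  covariates carry single-variable AUCs of ≈ 0.65 (size), 0.87 (habitat
  fraction) and 0.81 (peritumoral score) at ≈ 38% prevalence — the signal
  strengths the corresponding clinical, habitat and 3 mm peritumoral models
  reach in published dual-centre STAS cohorts of ≤ 2 cm solid
  adenocarcinomas. They are fixed; they are not tuned per experiment.

What the phantom does **not** emulate: real lung anatomy (airways, vessels,
fissures), scanner/platform differences and their batch effects, reader
variability in segmentation, non-ellipsoidal tumor shapes, and habitat
geometries other than sectors. Passing tests therefore demonstrate that the
pipeline recovers planted structure of this kind at these SNRs — not that
any particular AUC will be attained on patient data.

## Numerical and scale choices

- All randomness funnels through explicit integer seeds; cohorts are
  bit-reproducible, and per-patient render seeds derive from the cohort
  seed so labels do not depend on whether volumes are rendered.
- K-means uses 10 k-means++ restarts, 50 Lloyd/Hartigan–Wong iterations.
- Degenerate inputs are contracts, not accidents: empty masks error; rings
  that vanish after exclusion error with the case named; sub-2-voxel
  regions yield all-missing feature rows (imputed later); zero-variance
  columns are dropped with warnings; complete separation falls back to the
  Jeffreys-penalised fit; W = 0 in the CH index returns +∞ with a warning.
- Test-suite problem sizes are chosen for desk-scale verification: the
  habitat-count recovery study uses 20 replicate cohorts of 40 patients
  (the cohort size at which the CH curve is stable); the model-ordering
  study uses 20 replicates of 64 train/validation + 60 external-test
  patients in 44³ volumes (same tumors, less empty parenchyma), with the
  logistic family standing in for the full algorithm zoo. The published
  cohort sizes (217/93/91) are used where they are free (split arithmetic,
  label-model recovery at n = 1000).

## Known limitations

- The 19 voxel-level statistics and the 88 region features are fixed sets;
  filtered-image features and alternative window sizes are out of scope.
- Cross-patient habitat correspondence by intensity ranking is a
  convention; when subregions differ mainly in dispersion, not level, the
  ranking can be unstable and habitat feature blocks correspondingly noisy.
- The CH-selected habitat count reflects cluster geometry in the 19-feature
  space, not biology; on phantoms the modal selection equals the planted
  count, but per-cohort selections vary.
- Validation-split winner selection inflates validation AUCs (by design,
  following the source protocol); compare models on the external test split.
- The phantom's sector geometry makes subregion *fractions* the habitat
  signal carrier; recovered fractions are attenuated relative to truth, so
  habitat-model AUCs sit below the true-covariate ceiling.
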