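---
title: "Methods: CT white matter lesion segmentation with cross-modality labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT white matter lesion segmentation with cross-modality labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

White matter lesions (WML) — the imaging hallmark of cerebral small vessel
disease — are routinely graded on MRI FLAIR, where they are bright and easy
to see, using the visual Fazekas scale. Head CT is far more widely
available, but WML appear there only as subtle hypodensities. ctwml
implements a pipeline that learns to segment WML from CT using *labels
derived from the co-registered FLAIR of the same subject* (cross-modality
label transfer), and then asks two quantitative questions: do CT-derived
lesion volumes agree with FLAIR-derived volumes, and can a three-level
Fazekas grade (0–1 / 2 / 3) be recovered from the volume alone?

## Pipeline

1. **Brain extraction** (`extract_brain()`): Otsu threshold, largest
   6-connected component, hole filling. This is a deliberately simple
   stand-in for a clinical skull-stripping tool; phantoms are constructed
   so it is accurate (Dice > 0.95 against the generative mask).
2. **Spatial normalization** (`normalize_spatial()`): the binary brain mask
   is registered to a template mask with a 9-DOF affine (3 rotations, 3
   translations, 3 log-scales). Initialization is closed-form from mask
   centroids and per-axis second moments; polishing maximizes a soft Dice
   between Gaussian-smoothed masks (smoothing makes the objective sensitive
   below the voxel scale) with Nelder–Mead, two resolution levels, 200
   evaluations per level. The reported optimum is never worse than the
   identity or the moment initialization.
3. **Rigid CT→FLAIR registration** (`register_rigid_nmi()`): 6-DOF,
   maximizing normalized mutual information
   `NMI = (H(F) + H(M)) / H(F, M)` from a 32-bin joint histogram over the
   in-mask overlap. Optimization: coarse translation grid search, then
   Nelder–Mead at half and full resolution (200 evaluations per level).
   Both images are pre-smoothed by one voxel; without this, linear
   interpolation averages the moving image's noise wherever the sampling
   grid is off-lattice, which *sharpens* the joint histogram and biases NMI
   away from true alignment. The returned transform is never worse in NMI
   than the identity.
4. **Intensity normalization** (`zscore_in_mask()`): z-scoring within the
   brain mask, population-SD convention (the n–1 difference is immaterial
   at ~10^5 in-mask voxels but a convention must be fixed for exact
   idempotence tests). Out-of-mask voxels are set to 0.
5. **Segmentation network** (`model_spec()`, `train_cnn()`,
   `predict_probability()`): a residual U-shaped 2D CNN over 64 × 64 axial
   patches. Patches are 2D because clinical acquisitions of this kind have
   4–5 mm slices, which makes 3D kernels ill-posed. Default scale: 3
   resolution levels, 8 base channels (doubling per level), one residual
   unit per level, stride-2 convolutions down, nearest-upsampling with 1×1
   projection and additive encoder skips up, pixelwise binary cross-entropy
   on logits, Adam (lr 2e-3), 20 epochs, batch 16. The output bias is
   initialized to −2 to match the low lesion prior. All randomness (weight
   init, shuffling, patch sampling) is seeded. Whole volumes are predicted
   slice-by-slice with 50%-overlap tiling; each pixel's probability is the
   mean over covering tiles, and probabilities are zeroed outside the
   brain mask.
6. **Repeated cross-validation ensemble** (`make_fold_plan()`,
   `run_cv_ensemble()`): k-fold CV over subjects (default 10×10 at clinical
   scale; 3 folds × 3 repetitions at phantom scale), re-randomizing both
   fold membership and model initialization per repetition. Every subject
   is predicted exactly once per repetition by a model that never saw it;
   the final mask is the arithmetic mean of the per-repetition probability
   maps thresholded *inclusively* at 0.25. Folds are stratified by Fazekas
   group by default — with as few as 15 subjects per fold a non-stratified
   draw can produce training folds with no severe cases; the unstratified
   mode remains available (`strata = NULL`).
7. **Evaluation** (`overlap_stats()`, `volume_correlation()`,
   `bland_altman()`, `cross_validated_fazekas()`): Dice
   `2|X∩Y|/(|X|+|Y|)` (defined as 0 when both masks are empty, with a
   flag), correct/incorrect voxel volumes, Pearson correlation with an OLS
   line of CT volume regressed on FLAIR volume (the regression direction is
   a documented choice; a symmetric fit would also be defensible),
   Bland–Altman limits of agreement (population SD, 1.96 multiplier), and a
   two-threshold Fazekas classifier fitted by exhaustive search over
   midpoints of consecutive distinct volumes (plus 0 and +∞ sentinels),
   ties broken toward the lexicographically smallest `(t_low, t_high)`,
   evaluated by 10-fold cross-validation.

## The phantom generator

No public paired CT–FLAIR dataset with WML labels exists at the scale this
pipeline needs, so the package ships a generator (`phantom_spec()`,
`generate_pair()`, `generate_cohort()`) whose defaults define the study
conditions used throughout the tests:

- 64 × 64 × 24 grids at 2 × 2 × 4 mm — desk-scale, with the through-plane
  anisotropy of thick-slice clinical scans.
- An ellipsoidal brain (semi-axes 44/54/34 mm, jittered ±4% per subject)
  with smooth shared "anatomical" texture (sum of random Gaussian bumps),
  so that the two channels are related but not identical and rotations are
  identifiable by registration.
- Blob-shaped lesions confined to a periventricular/deep shell
  (normalized radius 0.25–0.7), radii 2–7 mm, with a smooth intensity ramp
  at the boundary. Lesion contrast is **+2.5** z-units on FLAIR
  (hyperintense) and **−1.2** on CT (hypodense, lower magnitude); noise is
  additive Gaussian, SD 0.3 (FLAIR) and 0.5 (CT). These values make CT the
  clearly harder modality without making it hopeless, which is the regime
  the method targets; the source setting prints no noise model, so
  additive Gaussian is the simplest choice exposing the contrast gap.
- Per-group total lesion loads drawn from 0–2 / 5–15 / 25–60 mL. Printed
  per-group volume ranges are not available anywhere, so these strata were
  chosen once as monotone, well-separated, and clinically plausible.
- A rigid misalignment of the CT channel, rotations ≤ 5°, translations
  ≤ 4 mm — plausible head repositioning, recoverable by rigid
  registration. CT noise is added *after* the misalignment resampling:
  acquisition noise belongs to the observed frame, and adding it before
  resampling would smooth it in a transform-dependent way.

What the phantoms deliberately do **not** contain: real anatomy (gyri,
ventricles), CT artifacts (beam hardening, streaks), lacunes or
microbleeds, scanner heterogeneity. Passing phantom tests therefore shows
that the pipeline's machinery is correct and well-calibrated under known
conditions — not that it would reach any particular accuracy on clinical
data.

## Numerical choices and degenerate inputs

- Resampling uses the pull-back convention (transforms map fixed-image
  world coordinates to moving-image world coordinates); out-of-field
  voxels become 0 (brain-extracted images are 0 outside the head). Masks
  must use nearest-neighbour interpolation (enforced), intensities use
  trilinear.
- Transforms carry their rotation centre (the fixed grid's world centre)
  so a recovered transform's parameters are directly comparable with an
  imposed one.
- Probability maps are written as 32-bit float, masks as uint8, intensity
  images as float64 (keeping write→read round trips exact).
- Thresholding is inclusive (`>=`); z-scoring uses population SD; Dice of
  two empty masks is 0; empty masks, all-zero volumes, constant
  intensities, and missing label classes raise typed errors rather than
  returning silent wrong answers.

## Problem sizes used by the test-suite and acceptance script

The cohort-scale checks run a 45-pair cohort (15 per group) through the
full chain with 3 folds × 3 repetitions at the default model scale and 224
patches (lesion fraction 1/3) per fold model; the acceptance script uses a
24-pair cohort with 3 folds × 2 repetitions, 12 registration-recovery
pairs, and the worked-example confusion matrices. The ensemble-robustness
check uses thinner 64 × 64 × 10 volumes and a depth-2, 4-channel network
over 5 ensemble seeds. These sizes were chosen so the whole suite runs on
a single CPU in well under half an hour while keeping every statistical
property it asserts comfortably away from its decision boundary.

## Known limitations

- The CT channel's intensities are not HU-calibrated and no HU windowing
  is applied before z-scoring; whether clinical practice would window
  first is an open question and a documented divergence.
- The 9-DOF normalization estimates scale from binary masks; at 4 mm
  slices its through-plane scale is only accurate to ~2%, which propagates
  into volume comparisons made *across* spaces (the pipeline therefore
  compares volumes within template space only).
- Training at desk scale uses a few hundred patches per model; the
  clinical-scale protocol (10 × 10 CV over 147 subjects, large patch
  counts) is the same code but has not been run inside this package.
- Whether the original protocol re-randomized fold membership across
  repetitions is not documented; this implementation re-randomizes both
  membership and initialization, which is the stronger ensemble.
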