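---
title: "Methods: radiomics and dosimetric analysis of post-radiotherapy recurrence"
author: "radrecur authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics and dosimetric analysis of post-radiotherapy recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

After intensity-modulated radiotherapy (IMRT) for nasopharyngeal carcinoma
(NPC), most treatment failures occur *inside* the high-dose volume: the
tumor regrows in a region that demonstrably received the prescribed dose.
Such in-field recurrence points to intrinsic radioresistance rather than a
geographic miss, and raises the question whether the pre-treatment MRI
already carries a signature that separates tumors that will recur in-field
(IFR) from tumors that will not progress (NPD).

`radrecur` implements the two halves of this analysis:

1. **Dosimetric recurrence-pattern classification.** Given a planning dose
   grid, a prescription dose and the recurrent tumor volume (V~recur~)
   registered onto that grid, the package evaluates the dose–volume
   histogram of V~recur~ at the 95 % prescription isodose and classifies
   the failure: *in-field* when at least 95 % of V~recur~ is covered,
   *marginal* when 20–95 % is covered, *out-of-field* below 20 %. Both
   boundary points are closed on the side the rule text implies (0.95 is
   in-field, 0.20 is marginal). Coverage is computed by voxel counting;
   sub-voxel partial-volume weighting would suggest precision the
   registered masks do not have.

2. **An MRI radiomics pipeline** that quantifies intratumoral texture
   heterogeneity on fat-suppressed T2-weighted (SPAIR T2W) images and asks
   whether it discriminates IFR from NPD tumors: preprocessing →
   1117-feature extraction → reproducibility/redundancy/significance
   selection → PCA → cross-validated classification.

Because no patient images are distributed, the package ships a synthetic
cohort generator that emulates the study conditions and carries known
ground truth; every stage is exercised end-to-end against it.

## Preprocessing

The acquisition grid is anisotropic (0.65 × 0.65 × 4 mm voxels), so the
volume and contour are first resampled to isotropic 1 mm³ voxels — the
image with tricubic (Keys) interpolation, the mask with trilinear
interpolation thresholded at 0.5. Nearest-neighbour mask resampling was
rejected because its stair-step artifacts corrupt shape features.

Within the contour the gray levels are normalized to the ROI band
[m − 3s, m + 3s] (m, s: ROI mean and standard deviation), voxels outside
that band are excluded from intensity statistics, and the band is mapped
by equal-width binning onto 64 levels (1..64), with a right-closed top bin
so the band endpoints land on levels 1 and 64. For Gaussian-like ROIs the
exclusion removes ≈ 0.27 % of voxels. The map is monotone and invariant
under positive affine intensity transforms, which is what makes texture
features comparable across scanners' arbitrary intensity scales.

Two ordering decisions were genuinely open and are fixed as follows:

* **Resample before quantize.** Quantized integer levels cannot be
  meaningfully interpolated, so normalization/quantization happens on the
  1 mm analysis grid. The [m ± 3s] semantics then refer to the grid on
  which textures are actually measured.
* **Fixed bin count, not fixed bin width.** The 1..64 codomain forces 6-bit
  quantization but not the rule; equal-width binning of [m − 3s, m + 3s]
  into exactly 64 bins is adopted.
* **Degenerate ROIs.** A constant ROI (s = 0) maps every voxel to level 1
  with a warning, so entropy-type features take their analytic limit 0.
* **Excluded voxels** are dropped from intensity and texture statistics but
  stay in the mask for shape features: shape is geometry, not intensity.

## Derived images

Eleven filtered derivatives are computed per case on the isotropic grid:

* **Laplacian-of-Gaussian** responses at σ = 0.5, 1.5, 2.5 mm (fine,
  medium, coarse texture enhancement). The operator is evaluated as the
  sum over axes of a sampled second-derivative-of-Gaussian kernel times
  Gaussian smoothing along the other axes, truncated at 5σ with a zero-sum
  correction, reflective boundaries. Its impulse response is therefore the
  analytic ∇²G kernel sampled at voxel centers, and affine images are
  annihilated exactly.
* **One-level undecimated 3D wavelet transform** with the Coiflet-1 filter
  bank and periodic boundaries, giving the 8 sub-bands LLL..HHH. Letters
  map to array axes in index order (HLL = high-pass along axis 1). The
  undecimated (stationary) variant is used precisely so every sub-band
  stays congruent with the grid and the ROI mask applies without
  resampling. Coiflet-1 at a single level follows the convention of the
  standard feature-extraction platforms for this feature family.

Each derived image is re-normalized and re-quantized within the ROI before
texture computation, since filter outputs live on their own intensity
scales.

## The 1117-feature manifest

Per case the default manifest is:

| block                        | count |
|------------------------------|-------|
| shape (original mask only)   | 13    |
| first-order                  | 18    |
| GLCM                         | 23    |
| GLRLM / GLSZM                | 16+16 |
| GLDM                         | 14    |
| NGTDM                        | 5     |

Original image: 13 + 18 + 74 = 105. Each of the 11 derived images: 18 + 74
= 92. Total 105 + 11 × 92 = **1117**. First-order and all five texture
families are computed on derived images as well — the significant-feature
nomenclature (for example `W_HLH__F_RMS`, `W_LLH__ngtdm_Strength`)
requires them to exist. Derived keys follow `<tag>__<family>_<name>`; an
abbreviation map ships as JSON (`feature_abbreviations()`), with `glcm_IMC`
resolving to informational measure of correlation 1 (IMC2 is also
computed under its own key).

Conventions that pin the numbers down:

* GLCM: the 13 unique 26-connectivity directions at distance 1 voxel,
  symmetric per-direction matrices, unweighted per-direction normalization,
  each feature averaged over directions. GLRLM likewise over the 13
  directions.
* GLSZM is computed once per image: size-zone matrices are built from
  26-connected equal-level zones and have no directional parameter.
* GLDM uses the 26-neighborhood at Chebyshev distance 1, zero gray-level
  tolerance; dependence size is 1 + the number of matching neighbors.
* NGTDM uses the 3 × 3 × 3 neighborhood mean differences.
* The gray-level axis always spans 1..64, not the observed levels, so
  features are comparable across cases.
* Texture matrices are filled in C++; every family is verified against an
  independent brute-force R oracle (explicit pair enumeration, flood fill)
  to 10⁻¹⁰ relative error in the test suite.
* Shape: volume is voxel count × voxel volume; the surface is the
  0.5-level set of the lightly smoothed mask indicator (σ = 0.7 voxels)
  triangulated by marching tetrahedra with interpolated crossings. Meshing
  the raw binary field instead overestimates a sphere's area by ≈ 28 %
  (staircase bias); with the smoothed field a digital ball of radius 10 mm
  lands within ≈ 1 % of 4πr², keeping sphericity in [0.97, 1.0].
  Principal-axis lengths are 4√λ of the voxel-coordinate covariance
  eigenvalues.

Any non-finite feature flags the case rather than silently dropping it.

## Feature selection cascade

The fixed order is ICC → PCC → Kruskal–Wallis/BH → ROC; each stage consumes
only the previous stage's survivors.

* **ICC filter.** Feature reproducibility across two delineations is
  scored with ICC(2,1) — two-way random effects, absolute agreement,
  single measures, the standard choice for rater agreement — computed from
  the ANOVA mean squares. Features with ICC < 0.8 ("excellent" cut-off)
  are removed; undefined ICCs (zero between-subject variance) are removed
  with a warning.
* **PCC pruning.** While any retained pair has |r| ≥ 0.80, the most
  correlated pair is taken and the member with the larger mean absolute
  correlation against all other retained features is dropped
  (lexicographic tie-break, dropping the later key). The survivors form a
  low-redundancy set.
* **Kruskal–Wallis + Benjamini–Hochberg.** Per-feature rank test of the
  IFR/NPD difference (tie-corrected H, χ² p-value with df = 1; the χ²
  approximation is standard at n = 27), BH step-up adjustment, significance
  at adjusted p < 0.05. Raw and adjusted p-values are both reported;
  significance gates on the adjusted value.
* **ROC.** For each significant feature: AUC as the rescaled Mann–Whitney
  statistic with half credit for ties, oriented so AUC ≥ 0.5;
  Hanley–McNeil standard error; 95 % CI truncated to [0, 1]; sensitivity
  and specificity at the Youden-optimal threshold, ties resolved toward
  the lower threshold.

## Dimensionality reduction and classification

The significant features are standardized and reduced by PCA to the
smallest number of components reaching 85 % cumulative explained variance;
component signs are fixed by making each loading's largest-magnitude entry
positive, so results do not depend on eigensolver sign conventions.

Three classifiers are evaluated by stratified 10-fold cross-validation:

* **ANN** — `nnet`'s single-hidden-layer perceptron with
  ⌈(k + 2)/2⌉ hidden units, logistic activations, up to 500 iterations and
  a small weight decay (10⁻⁴). `nnet` optimizes by BFGS, so
  learning-rate/momentum knobs of stochastic trainers do not apply here.
* **KNN** — k = 3, Euclidean metric on the component scores.
* **SVM** — linear kernel, C = 1 (`e1071`).

Folds are assigned by class-wise round robin after a seeded shuffle —
deterministic and balanced for 11 + 16 cases in 10 folds, with both classes
present in every training set. Metrics (TP rate, FP rate, precision,
F-measure, MCC, accuracy) come from the confusion matrix pooled across
folds, with the weighted per-class convention under which the weighted TP
rate equals accuracy for two classes.

**Leakage.** By default standardization and PCA are refit inside each
training fold and applied to the held-out fold. A `paper_faithful = TRUE`
flag instead fits PCA once on the full table before splitting —
reproducing the common (but leakage-prone) protocol in which components
are derived from all cases — and is provided for comparison only. Cases
are internally processed in a canonical id order so results are invariant
to row order, and the whole CV is bit-for-bit reproducible given the seed.

## The synthetic cohort

The generator is the package's stand-in for the study cohort, with
defaults fixed at the study conditions: 11 IFR and 16 NPD cases on a
48 × 48 × 12 grid of 0.65 × 0.65 × 4 mm voxels. Each tumor volume is a
Gaussian random field — white noise convolved with an isotropic Gaussian
kernel of the class's correlation length — plus a constant offset (100)
and additive noise (SD 0.2, small against the smoothed-field amplitude).
IFR tumors get the shorter correlation length (1.5 mm vs 4 mm): the
planted signal is finer, more heterogeneous texture, the physiologic
difference the radiomic analysis is meant to detect. The absolute
intensity scale is irrelevant by construction, since the [m ± 3s]
normalization removes scale and offset. ROIs are ellipsoids (9 mm
semi-axes, ±10 % per-case jitter, ±1 mm center jitter) kept strictly
inside the grid. Each case draws from its own RNG stream keyed by
(seed, class, index), so enlarging the cohort never reshuffles existing
cases.

A second-observer contour is simulated by displacing the mask boundary
with a smooth random signed-distance offset bounded by 1 mm (Dice with the
original ≥ 0.8 up to 2 mm), standing in for repeated manual delineation in
the ICC stage. Dose cases are smooth radially decreasing fields scaled so
a requested fraction of the recurrence sphere sits inside the 95 %
isodose, with the achieved fraction stored as ground truth (a tiny
strictly monotone lattice perturbation removes radius ties so any target
fraction is reachable to voxel granularity).

What the generator does *not* emulate: MR pulse-sequence physics, bias
fields, anatomy, partial-volume mixtures at tissue interfaces, or
inter-scanner batch effects. Passing tests therefore demonstrate that the
pipeline's machinery is correct and powerful against a controlled planted
signal — not that the clinical effect size is reproduced. The separation
the default cohort plants is deliberately strong (single features reach
AUC near 1), which is what a power property needs; clinical AUCs in the
0.7–0.85 range are weaker than this synthetic regime.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
default 27-case cohort across 20 and 5 seeds respectively; single-case
extraction of all 1117 features takes well under a second at these grid
sizes. Oracle-equivalence checks use 50 random 8³ ROIs at 6 gray levels.
Gaussian kernels are truncated at 5σ; wavelet filters use periodic
boundaries (undecimated transform); resampling clamps cubic support at the
grid edge, so a one-voxel boundary ring is excluded from interpolation
accuracy guarantees. All RNG flows through explicit seeds; the pipeline is
a pure function of its configuration.

## Known limitations

* The feature set follows the widely used open-source radiomics taxonomy
  (13/18/23/16/16/14/5 per family, totalling 1117 with the 11 derived
  images); other platforms count slightly different members per family.
* The ICC stage uses the simulated second observer for all 1117 features;
  with real data the second delineation would come from a human rater.
* Surface area is mesh-based on a smoothed indicator; very thin or
  single-voxel structures are below its resolution (degenerate cases are
  reported with warnings).
* The dosimetric module consumes pre-registered masks; image registration
  is out of scope by design.
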