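---
title: "Quantifying the tumor-fat interface volume: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the tumor-fat interface volume: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biomarker and the problem it addresses

Adipocytes adjacent to a breast tumor act on it in a paracrine manner, and
direct tumor-fat contact has been proposed as a predictor of a poor
pathologic response to neoadjuvant chemotherapy (NAC). The biomarker this
package quantifies is the **tumor-fat interface volume**: the volume of fat
in direct face contact with tumor on pretreatment dynamic contrast-enhanced
(DCE) breast MRI. Operationally, on a voxel label map with classes
{background, fat, fibroglandular tissue, tumor}, the interface is the set of
**fat voxels having at least one tumor voxel among their 6 face-adjacent
neighbours** (one step along exactly one axis in 3D). Its volume is the
voxel count times the voxel volume, reported in cm^3^.

Two deliberate readings are fixed here and asserted by tests:

* *Face adjacency, not a wider neighbourhood.* 6-adjacency is by definition
  face connectivity; a larger radius would contradict the idea of a direct
  contacting plane.
* *The fat-side set.* The set of fat voxels touching tumor and the set of
  tumor voxels touching fat generally differ; the interface is defined on
  the fat side, and an asymmetric fixture in the test suite pins that choice.
* *Counts, not surface areas.* The quantity is a volume (count x voxel
  volume), not a marching-cubes surface-area estimate, because that is how
  the biomarker is defined and reported in cm^3^.
* *Grid borders.* Out-of-bounds neighbours are treated as background, the
  only definition that needs no padding assumption.

The patient images behind the original development (n = 1004) and external
validation (n = 136) cohorts are not public. The package therefore pairs the
measurement pipeline with two synthetic generators — an imaging phantom with
known voxel-level ground truth, and a cohort simulator with a known outcome
model — so that every stage can be validated by recovery of known truth, and
it ships the published contingency counts from which every unadjusted odds
ratio of the original report can be recomputed exactly.

# The measurement pipeline

## Chest-wall interpolation

Manual chest-wall delineation is performed on every fifth slice. The
package reconstructs a full wall surface by linear interpolation: across
columns within an annotated slice (through the polyline vertices), then
linearly along the slice axis per left-right column. Contours that are not
functions of the left-right coordinate (self-folding) are rejected with the
slice named, rather than silently averaged.

## Breast search region

The search region is the body tissue strictly anterior to the wall. Air is
excluded by a global two-class intensity split of the pre-contrast channel:
1-D k-means with two centres, thresholding at the midpoint of the centres.
An empty mask is always an error, never a silent empty result.

## Two-stage tissue clustering

Tissue separation uses k-means in two stages rather than a single k = 3:

1. **Fat vs non-fat** on the pre-contrast fat-suppressed channel. Under fat
   suppression, fat is the *lowest*-mean tissue, so the lower-mean cluster
   is fat.
2. **Tumor vs fibroglandular** on the subtraction channel (post-contrast
   minus pre-contrast at the early phase), restricted to non-fat voxels.
   Only tumor enhances strongly, so the higher-mean cluster is tumor.

The staging encodes the order in which the two channels carry information
(the pre-contrast image discriminates fat from non-fat; the enhanced image
separates tumor from parenchyma) and makes the procedure robust to the two
channels having unrelated intensity scales. Cluster-to-tissue assignment is
always by cluster-mean ordering, never by cluster index, which makes labels
invariant to initialization and to any monotone affine rescaling of a
channel; a test asserts both properties. Each channel is standardized
within its voxel set before clustering — with staged 1-D problems this is
nearly moot, but it protects against pathological dynamic ranges.

Numerical choices: `stats::kmeans` (Hartigan-Wong) with 10 restarts,
100-iteration cap, and a caller-supplied seed. For 1-D two-cluster
standardized data, restarts reliably reach the optimal partition, so a
k-means++ style initialization would change nothing; determinism for a
fixed seed is what matters and is tested. Degenerate inputs (constant
channel, empty cluster, no enhancing tissue) raise stage-specific errors.

Deliberately **not** implemented: suppression of tumor mimics (vessels,
strong background parenchymal enhancement). The original method reports
these as a known limitation rather than a processing step, and the phantom
does not emulate them — see *Limitations*.

# The imaging phantom

`generate_phantom()` builds a label volume first and renders intensities
from it, so ground truth is exact by construction:

* **Geometry.** A breast dome (half-ellipsoid) rests on a smooth chest-wall
  sheet, quadratic in the left-right coordinate and *linear along the slice
  axis*. Linearity in the slice direction is a deliberate idealization: it
  makes every-fifth-slice annotation lossless under the linear
  interpolation the pipeline uses, so noiseless end-to-end recovery is
  exactly Dice 1 and any failure in those tests is a real defect, not a
  discretization artifact. The final slice is always annotated so the
  surface covers the full stack.
* **Compartments.** A central fibroglandular sub-dome is scaled to meet the
  requested fat fraction (default 0.6); the remainder of the dome is fat.
* **Tumor and contact control.** Ellipsoidal tumors (isotropic in mm) are
  centred in the fibroglandular compartment. A shell of configurable
  physical thickness (default 3 mm) around each tumor is repainted by an
  azimuthal-wedge rule so that a chosen fraction `tumor_margin_contact` of
  the tumor surface touches fat: 0 isolates the tumor completely (ground
  truth interface exactly 0, a tested invariant), 1 embeds it fully in fat.
* **Intensities.** Per-tissue means with independent additive Gaussian
  noise per channel; the post-contrast volume is pre + subtraction exactly,
  so the subtraction invariant holds bitwise. Defaults (pre: air 0, fat
  100, chest 130, tumor 140, fibroglandular 150; subtraction: air 0, chest
  5, fat 10, fibroglandular 40, tumor 180; noise sd 10) place the smallest
  tissue separation — fat vs fibroglandular on the pre-contrast channel, 50
  units — at five noise standard deviations. Scanner protocols for the
  original cohorts are not available, so these scales are nominal, not
  calibrated to any device.
* **Default grid.** 64 x 128 x 128 voxels at 3 x 0.8 x 0.8 mm — anisotropic
  like clinical axial breast MRI and small enough that a full generate +
  segment + measure cycle runs in about 1.5 s, which is what keeps the
  20-seed recovery sweeps in the test suite inside a minute.

What the phantom does *not* emulate: MR physics (relaxometry, coil
sensitivity, bias fields are off by default), motion, bilateral anatomy,
vessels and enhancing parenchyma, non-mass enhancement, multifocality
beyond simple multi-lesion placement. Consequently, passing recovery tests
demonstrates the correctness of the *algorithmic chain* — wall
interpolation, masking, clustering, counting — on images whose contrast
structure matches the fat-suppressed/subtraction convention; it does not
demonstrate robustness to the mimics and artifacts of clinical data.

# The cohort simulator

`simulate_cohort()` draws clinical covariates independently from marginals
matched to the development cohort (age ~ 47.5 y; stage frequencies,
receptor prevalences, menopausal status at the reported proportions) and an
interface volume from a log-normal with median 1.80 cm^3 and sdlog 0.913,
which reproduces the reported median and approximates the reported
interquartile range (1.01-3.46 cm^3). Covariate independence is a modelling
choice — the original study reports no covariance structure — and it makes
marginal and conditional odds ratios nearly coincide except for
non-collapsibility.

The outcome (non-pCR) follows a logistic model whose linear predictor uses
the *dichotomized* interface indicator `I(volume >= 2.36 cm^3)` internally
while the emitted table carries the continuous volume; the analysis
pipeline performs its own dichotomization, mirroring the real design where
the cutoff is derived, not given. The default effect pattern follows the
published multivariable estimates (T3 2.122, T4 5.655, N3 2.237,
HER2-negative 5.002, high interface 1.412, intercept -1.0 for a marginal
non-pCR rate near 63%).

One subtlety matters for parameter-recovery experiments: with several
nonzero effects, the *univariable* (marginal) interface odds ratio differs
from the conditional generative one by non-collapsibility of the odds
ratio. Recovery of the marginal OR is therefore assessed under a generative
model in which the interface is the only nonzero effect (truth 1.6, near
the published univariable 1.626, with intercept 0.3 giving the observed
~62% non-pCR rate), and recovery is measured on the log-odds scale (the
scale on which the estimator is asymptotically unbiased); conditional
effects are recovered multivariably in separate tests. With 1000 replicates
at n = 1004 the Wald 95% CI covers the truth at the nominal rate
(93-97% observed).

# The statistical toolbox

All conventions match the original analysis and are documented on each
function:

* **Event coding**: non-pCR is the modelled event throughout; reported odds
  ratios are factors *for* non-pCR (e.g. HER2-negative OR > 1).
* **2x2 odds ratios** with Wald 95% CIs on the log scale
  (z = 1.95996, SE = sqrt(1/a + 1/b + 1/c + 1/d)); zero cells are an error —
  continuity corrections are out of scope.
* **Youden's J cutoff**: candidates are the observed distinct marker
  values, the rule is "value >= cutoff predicts the positive class", ties
  take the smallest cutoff. The validation cohort always reuses the
  development cutoff; the pipeline enforces this.
* **Logistic regression** by IRLS (tolerance 1e-8, 100 iterations) with
  Wald z-tests per coefficient and a likelihood-ratio p-value per
  predictor; the p < 0.05 univariable entry rule; the composite molecular
  subtype is excluded from the multivariable model when its components
  (ER/PR/HER2) are themselves selected, because it is a deterministic
  function of them.
* **VIF** per design column as 1/(1 - R^2), flagged above 5. Indicator
  columns of one multi-level factor can exceed 5 structurally when the
  reference level is rare; that reflects reference coding, not
  between-predictor collinearity.
* **DeLong test** for paired ROC curves (midrank AUCs, placement-value
  covariance); exactly identical score vectors are reported as p = 1, the
  natural limit of a zero difference with zero estimated variance.
* **NRI and IDI** in the *continuous (category-free)* form — the original
  report names no risk categories, so the category-free version is the only
  faithful reading; this interpretation is switchable in principle and is
  documented on the function. Standard errors are the usual asymptotic ones
  (multinomial for NRI, delta-method for IDI); a percentile bootstrap is
  available behind a flag.
* **ICC** fixed to ICC(2,1) — two-way random effects, absolute agreement,
  single measure — computed from the two-way ANOVA mean squares. The
  original report does not state its ICC model; ICC(2,1) is the standard
  choice for "same subjects, interchangeable random readers, absolute
  agreement", and the form is stated everywhere a value is reported.
* **Group comparisons**: Wilcoxon rank-sum (normal approximation, tie
  correction) for continuous variables; chi-squared, or Fisher's exact test
  when any expected cell is below 5, for categorical ones.

# Problem sizes used in the shipped experiments

The test suite and the acceptance script run: phantom recovery on the
default 64 x 128 x 128 grid (one noiseless phantom, plus 20 noisy seeds
with the smallest tissue separation set to exactly 4 noise standard
deviations); oracle equivalence on fifty random 20^3 label fields and one
hundred random cutoff datasets of n = 50; and cohort calibration with 1000
replicates of n = 1004. These sizes give sub-minute module tests while
keeping Monte-Carlo error well below the tolerances being asserted (the
coverage estimate, for instance, has a standard error of about 0.7
percentage points at 1000 replicates).

# Known limitations

* The clustering reconstruction is a declared interpretation: the original
  appendix detailing the search region and clustering is not available in
  the text this package was built from, and whether clustering ran on raw
  or normalized intensities is unstated. The two-stage design follows the
  published figure narrative (fat/non-fat on the pre-enhanced image, then
  tumor/fibroglandular on the enhanced image) and is robust to either
  normalization choice by construction.
* Whether the original implementation counted fat voxels or contact faces
  is not fully disambiguated by the text; this package counts fat voxels,
  following the definition of the interface as a collection of fat pixels.
* The multivariable coefficients of the original tables are not exactly
  reproducible anywhere: they require patient-level data. They are covered
  structurally (parameter recovery on simulated cohorts), not numerically.
* One printed CI pair (validation-cohort Ki-67, 1.260-25.556) differs from
  the Wald computation on its own printed counts in the third decimal on
  both bounds (computed: 1.259-25.560), consistent with intermediate
  rounding in the original report; the other nine printed CI pairs
  reproduce exactly to three decimals.
* Phantom realism bounds what recovery tests can show; see the phantom
  section. In particular the simulated interobserver study perturbs only
  the chest-wall contours, so its ICCs are an upper bound on real
  inter-reader agreement.
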