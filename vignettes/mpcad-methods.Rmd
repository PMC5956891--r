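---
title: "Multi-scale radiomics detection in MP-MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale radiomics detection in MP-MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mpcad` detects and localizes tumours in multi-parametric MRI (MP-MRI) of
the prostate by combining three models that operate at different spatial
scales. This vignette explains the science behind each stage, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and what the synthetic phantom validation does and
does not demonstrate.

## Imaging models

The pipeline consumes a T2-weighted volume plus a diffusion-weighted (DWI)
stack acquired at b = 0, 100, 400, 1000 s/mm² and derives four more
channels, for nine co-registered volumes per patient:

* **ADC** — the apparent diffusion coefficient D is fit per voxel from the
  mono-exponential decay S = S₀·exp(−b·D) by ordinary least squares of
  ln S against b. Signals are clipped to a floor (1e-6) before the
  logarithm; voxels dark at every b-value are flagged invalid and given
  D = 0; negative slope estimates (possible under noise) are clamped to
  zero. The fit is exact on noiseless input.
* **CHB-DWI** — a computed high-b image, extrapolating the same log-linear
  fit to b = 2000 s/mm². High-b images sharpen the tumour/healthy contrast
  but are rarely acquired directly. An optional ridge weight on the decay
  slope is available for noisy data; the default is the plain
  least-squares extrapolation, which has the identical point estimate in
  the noiseless limit.
* **CDI** — correlated diffusion imaging mixes the signal across all
  b-values over a local subvolume. The joint density over the subvolume
  is realized as a normalized isotropic Gaussian kernel (σ = 2 mm,
  configurable) applied to the per-voxel cross-b-value signal product; a
  zero radius degenerates to the plain product. The kernel is
  renormalized at image borders, so constant fields are preserved.
* **Relative ADC** — absolute peripheral-zone ADC varies between patients;
  the ratio of a region's ADC to its local surround correlates better
  with malignancy. Each candidate region of interest is dilated in-plane
  with a disc structuring element (radius 3 voxels); the dilated region
  is divided by the median ADC of the surrounding band, overlaps are
  resolved by nearest-centroid ownership, and everything outside the
  dilated regions is divided by the mean of the surround medians. The map
  is invariant to global rescaling of the ADC map by construction.
  Regions with a zero-median or empty surround are skipped with a
  warning. Before any candidates exist (e.g. when a phantom is
  generated), the stored rADC channel is normalized against the gland's
  own surround; the pipeline recomputes the candidate-driven map once
  stage 1 has produced regions.

## Stage 1: voxel-resolution textural distinctiveness

Every gland voxel is described by a 96-feature texture bank (Table-style
inventory: 4 first-order window statistics, 72 grey-level co-occurrence
statistics — 18 Haralick-family statistics at 4 in-plane directions, min–max
window quantization to 32 levels —, 12 Gabor magnitudes over 3 wavelengths
× 4 orientations, and 8 Kirsch compass responses). The source channel of
each operator group is configurable; the default evaluates the intensity
statistics on ADC, the Gabor bank on T2w and the Kirsch bank on CHB-DWI,
which keeps the inventory at exactly 96 while leaving the group-to-channel
mapping open — the channel attribution of the 96 features is ambiguous in
the source material. Windows are 5×5 in-plane (processing is 2-D per
axial slice), clipped at borders; degenerate windows receive explicit
finite fallbacks (energy 1, entropy 0, contrast 0, correlation 0) so the
matrix is always finite. The pipeline evaluates the bank on the gland
interior eroded in-plane by the window half-width: windows straddling
the gland capsule mix in-gland and out-of-gland tissue and generate
extreme partial-volume texture atoms that crowd genuine tissue patterns
out of the sparse model.

The bank is z-scored and compacted by PCA to the smallest number of
components explaining 90% of the variance. A sparse texture model of m = 8
Gaussian atoms (mean, covariance, weight) is then learned by EM with
k-means++ initialization, a 1e-6 covariance ridge, and convergence when
the mean per-voxel log-likelihood gain falls below 1e-6 (cap 500
iterations). Because a single initialization occasionally converges to a
poor local optimum whose atom structure is dominated by one outlier
pattern, three short initialization runs (30 iterations each, seeds
derived from the model seed) are compared by log-likelihood and the best
is continued to convergence — likelihood-based restart selection,
standard for mixture fitting. m is not prescribed by the method, only
that it be far smaller than the voxel count; 8 is the default and
configurable.

The distinctiveness of two atoms is the Kullback–Leibler-type divergence

β(i,j) = log(|Σⱼ|/|Σᵢ|) − u + tr(Σⱼ⁻¹Σᵢ) + ½(μⱼ−μᵢ)ᵀΣⱼ⁻¹(μⱼ−μᵢ),

in which only the Mahalanobis term is halved — `kl_distinctiveness`
implements this form verbatim. Atom saliency combines β with the atom
occurrence probabilities P on the test patient. Two index conventions
exist for the probability factor: αᵢ = Pᵢ·Σⱼ β(i,j) (the form
`compute_saliency` defaults to) and αᵢ = Σⱼ β(i,j)·Pⱼ. The first weights
an atom's distinctiveness by **its own** abundance, which suppresses
exactly the rare, distinctive patterns the stage exists to flag; the
second scores a rare atom by how strongly it differs from the *abundant*
patterns. Because suspicious tissue is by assumption rare and distinct,
the pipeline configuration uses the second (j-indexed) form by default
(`mpcad_config()$rd_std$saliency_prob_index`); both are available and the
switch is a single config entry. Voxels are assigned to their
maximum-responsibility atom, and an atom's voxels are salient iff its
saliency strictly exceeds half the maximum.

Candidate regions are per-slice 8-connected components **of each texture
atom's voxels** with at least 10 voxels. Extracting components per
texture set rather than from one union mask keeps texturally different
but spatially adjacent voxels from merging into one gland-sized blob.
By default every atom proposes candidates: whether a particular atom
clears the half-max saliency cut is sensitive to the heavy tail of the
distinctiveness distribution (one extreme atom can monopolize the
threshold), and stage 1's job is to miss nothing — the region model does
the discrimination. The saliency labelling itself remains the stage's
voxel-resolution output, and a config switch
(`rd_std$candidates_from = "salient_atoms"`) restricts candidacy to
atoms passing the half-max rule.

## Stage 2: region-resolution feature model

Each candidate region receives 242 named features: 3 morphology + 4
asymmetry + 1 size (shape-only, identical across channels) and 26
physiology features × 9 channels.

* **Morphology.** f₁ is the normalized area difference between the
  morphological closing and opening with one disc structuring element
  (radius 2). f₂ resamples the traced boundary to 128 equidistant points
  and measures the relative perimeter drop after truncating the Fourier
  descriptors to 8 harmonics; the reference perimeter is itself taken at
  a 16-harmonic reconstruction, because the pixel staircase of any
  rasterized boundary otherwise registers as irregularity (a digitized
  circle carries ≈6% staircase perimeter). f₃ rasterizes 2-harmonic and
  16-harmonic reconstructions and reports their symmetric-difference to
  union area ratio. The cut-offs are not prescribed by the method;
  defaults are exposed as arguments.
* **Asymmetry.** The region is split through its centroid along each
  principal axis of its second central moments; each split yields
  (A_large − A_small)/A_norm with A_norm either the whole area or the
  smaller half (4 features). Pixels exactly on the split line count half
  to each side, so symmetric shapes score exactly 0; a degenerate empty
  half caps the smaller-half variant at 10.
* **Physiology.** 7 first-order statistics over the in-region pixels plus
  19 statistics of one region-global GLCM built from horizontal adjacent
  pixel pairs in which both pixels lie inside the region (32 grey levels,
  min–max over the region, symmetric, normalized). The 19th statistic is
  the entropy normalized by its maximum log₂(32²). The GLCM is global
  over the region, not windowed: region-scale heterogeneity is the
  signal of interest.
* **Size.** Voxel count × in-plane voxel area (mm²).

Feature selection is two-stage and criterion-driven. Stage 1 ranks each
channel's 26 physiology features by greedy mRMR (mutual information with
the label minus mean mutual information with already-selected features;
equal-frequency 10-bin discretization) and picks the prefix length (grid
1–26) whose RBF-SVM maximizes the chosen criterion — sensitivity,
specificity, or AUC — on the training regions; the 8 shape features are
one further group (grid 1–8). Stage 2 pools the survivors, re-ranks and
picks the final prefix the same way. The grid is scored by resubstitution
on the training regions with ties broken toward the smaller subset; all
selection happens strictly inside the training patients of each fold.
Training labels call a region positive when at least 50% of its area
overlaps the voxel truth mask (configurable; region-level ground truth is
not otherwise defined). The classifier is an RBF-kernel SVM (C = 1,
γ = 1/d) on z-scored selected features with inverse-frequency class
weights — the candidate stage is sensitivity-first, so true positives are
a small minority of the training regions and an unweighted fit collapses
to the majority class.

## Stage 3: relative-ADC-driven CRF refinement

The conditional random field refines the stage-2 labels at voxel
resolution on each slice containing candidates. Unary costs are the
negative log of the region classifier's probability (logistic squashing
of the margin score; background voxels get p = 0.01; costs clamped at
1e6). The pairwise term is a contrast-sensitive total-variation penalty
over 4-neighbour in-plane cliques, w·exp(−‖fᵢ−fⱼ‖²/2σ²)·|yᵢ−yⱼ|, where f
are the per-voxel texture features of the **relative-ADC** channel: the
full 96-column bank evaluated with every operator group on rADC, then
PCA-compacted to 90% variance. σ defaults to the median pairwise feature
distance over the edges, w to 1.

The energy is minimized over the relaxed field Y ∈ [0,1]ⁿ by projected
gradient descent. The relaxed objective (linear unary + weighted total
variation) is convex and attains binary minimizers, so descent plus
thresholding at 0.5 is in principle exact. Two numerical devices make it
reliable in practice: the |yᵢ−yⱼ| kink is smoothed as √(d²+ε) with ε
graduated over stages 1e-2 → 1e-4 → 1e-8 (blocks of coupled voxels can
slide jointly before the kink hardens; the recorded energy trace remains
non-increasing within and across stages because shrinking ε only lowers
the energy), and the thresholded labels receive a greedy single-flip
polish on the exact discrete energy. On random 3×3 problems the result
matches exhaustive 2⁹ enumeration. The step is halved whenever a move
would increase the energy and regrown by 1.5× (capped at 8× the initial
step) after accepted moves. Refinement can only shrink the stage-2
positive mask in this pipeline — the final mask is intersected with the
stage-2 mask — so voxel-level false positives never increase.

## The synthetic phantom

Clinical MP-MRI with annotated ground truth cannot ship with the package,
so validation runs on a parametric phantom that reproduces the *structure*
of such data: a 48×48×8 volume at 1.56×1.56×3 mm containing an
ellipsoidal gland (semi-axes 15×11×2.8 voxels), zero or more ellipsoidal
lesions, a smooth S0 field with a 10% in-plane drift emulating coil
shading, and Rician magnitude noise (σ = 15 against S0 = 1000, i.e.
roughly SNR 67 at b0 and 13 at b1000). DWI channels follow the
mono-exponential decay with D = 1.6×10⁻³ mm²/s in gland tissue,
1.0×10⁻³ outside, and 0.7×10⁻³ inside lesions — typical peripheral-zone
versus tumour magnitudes; lesions are also T2w-hypointense (contrast
factor 0.6). Tissue boundaries are blended with a 2-voxel Gaussian
truncated at 3σ, so parameter values away from boundaries are exact and
recoverable to machine precision from a noiseless phantom. Derived
channels are computed from the noisy acquisitions by the same estimators
used on real data. Everything is deterministic given the seed.

What the phantom does **not** emulate: anatomical zonal structure,
scanner distortion and bias fields, registration error between channels,
lesion texture heterogeneity beyond the ADC/T2w mean contrast, and
multi-focal or non-ellipsoidal disease. Passing the end-to-end phantom
suite therefore demonstrates that the pipeline machinery is correct and
that the stages interact as designed (sensitivity-first candidates,
specificity-restoring classification, refinement that never adds false
positives) — it does not certify clinical performance, which in the
source study depended on a 30-patient cohort that is not distributable.

## Study sizes and runtimes

The cohort-level checks use 10 phantoms (5 with one lesion each) under
leave-one-patient-out cross-validation, pooling roughly 15,000 training
voxels per fold for the texture model (subsampled from ~20,000 gland
voxels) and a few dozen candidate regions per fold for the region model.
These sizes were chosen so a full study runs in minutes on one core while
every stage still sees realistically imbalanced data; they are
configurable (`mpcad_config`).

## Known limitations

* 2-D in-plane texture operators only; thick slices make 3-D texture of
  limited value at this resolution, but the bank is not extensible to 3-D
  without new code.
* The CDI joint-density kernel and the CHB-DWI ridge stand in for
  estimator details that are not fully specified in the source method;
  both are configurable and documented above.
* The stage-1 grid in feature selection is scored by resubstitution; with
  larger cohorts a nested grouped CV would be preferable and can be added
  behind the same interface.
* Patient-level decisions use a simple positive-region count threshold
  (k = 1 by default); no lesion-level confidence calibration is done.
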