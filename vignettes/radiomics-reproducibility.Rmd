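---
title: "Methods: PET radiomic feature reproducibility with radrepro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomic feature reproducibility with radrepro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrepro)
```

## The problem

Radiomic features — texture, shape and intensity descriptors extracted
from masked tumor volumes on PET images in SUV units (g/ml) — are only
useful as biomarkers if they are stable under the arbitrary choices made
upstream of the feature extractor. `radrepro` quantifies feature
reproducibility under three such choices:

* **Segmentation method (SM)** — who (or what) drew the tumor mask:
  two manual observers (labels `MTV1`, `MTV2`) and a semiautomatic
  graph-based volume (`GBSV`).
* **Gray-level discretization (GL)** — the fixed bin count
  $N_g \in \{32, 64, 128, 256\}$ used to re-bin ROI intensities, with 64
  as reference.
* **Reconstruction algorithm (RA)** — the image-formation variant
  (`OSEM` reference, `FOREIR`, `FOREFBP`, `3DRP`), emulated here by
  smoothing/noise profiles.

Because no patient scans are deposited with the design this package
follows, a first-class synthetic phantom module supplies cases with the
statistical structure the analysis assumes.

## Feature extraction

### Discretization

In-mask SUVs are re-binned into $N_g$ equal-width bins over the ROI's own
range:
$$\text{bin size} = \frac{SUV_{max} - SUV_{min}}{N_g},\qquad
  \ell(v) = \min\!\left(N_g,\ \Big\lfloor\frac{SUV(v) - SUV_{min}}
  {\text{bin size}}\Big\rfloor + 1\right).$$
Extrema are taken inside the mask (the tumor volume is what gets
discretized, not the whole image). The $\min(N_g,\cdot)$ keeps the ROI
maximum in the top bin. A constant ROI has zero range; every voxel is
assigned level 1 with a warning so downstream matrices stay defined.
Whether the "original" 256 gray levels of a scanner image are a
re-binning or raw quantization is ambiguous; here 256 is treated as
$N_g = 256$ re-binning like any other level.

### Texture matrices (53 features)

All four families work on the discretized ROI; gray-level weights use the
bin indices $1..N_g$ and entropies are in bits.

* **GLCM (26)** — co-occurrences of level pairs at one-voxel displacement
  along the 13 unique 3D directions, pooled into a single symmetric
  matrix and normalized. Pooling (rather than averaging 13 per-direction
  feature sets) is a convention: the design source states only that 13
  directions are used. A single-row direction matrix switches to
  per-direction work. The feature list is the Haralick family completed
  to 26 (joint maximum/average/variance/entropy, difference and sum
  statistics, energy, contrast, dissimilarity, ID/IDN/IDM/IDMN, inverse
  variance, correlation, autocorrelation, cluster tendency/shade/
  prominence, IMC1/IMC2, maximal correlation coefficient).
* **GLRLM (11)** — maximal same-level runs along each direction, broken
  at mask boundaries, summed over directions. Run percentage is
  normalized by (directions × voxels) so the all-unit-runs limit is
  exactly 1. Galloway/extended list: SRE, LRE, GLNU, RLNU, RPC, LGRE,
  HGRE, SRLGE, SRHGE, LRLGE, LRHGE.
* **GLSZM (11)** — connected components of equal-level voxels under
  26-connectivity (zones are 3D clusters; 6-connectivity is switchable).
  Thibault list: SAE, LAE, IV, SZV, ZP, LIE, HIE, LISAE, HISAE, LILAE,
  HILAE.
* **NGTDM (5)** — per-voxel deviation from the mean of in-mask neighbors
  in a 7×7 *in-plane* window (the window is 2D per the stated pixel
  neighborhood, despite 3D ROIs; a 3D window is available via
  `window_halfwidth`). Voxels with no in-mask neighbor are skipped.
  Amadasun–King coarseness, contrast, complexity, busyness, strength,
  with an $\varepsilon = 10^{-12}$ guard: a flat ROI saturates
  coarseness at the sentinel $1/\varepsilon$.

The exact identity of all 26/11/11 members is not canonical in the
source design; beyond the named members the families are completed from
the standard catalogues above, and that completion is a documented
convention of this package.

### Shape (6 catalogued) and intensity (20)

Shape descriptors depend only on the mask: volume (voxel count × voxel
volume), mesh surface area, sphericity $\pi^{1/3}(6V)^{2/3}/A$, spherical
disproportionality $1/\text{sphericity}$, convexity, eccentricity
$\sqrt{1-\lambda_{min}/\lambda_{max}}$, and surface-to-volume ratio. The
design source counts six shape features in its methods and seven in its
results; the catalogue here counts six (volume included) while the
`shape_features()` summary additionally exposes the raw surface area.

Numerical choices:

* Surface area comes from a marching-tetrahedra iso-surface at level 0.5.
  On a raw binary field this mesh inherits voxelization staircase and
  overestimates a ball's area by ~25%, so the field is pre-smoothed with
  a small Gaussian (default 0.7 voxels, calibrated once on analytic
  balls where it keeps the error within ~1% for radii ≥ 10 voxels). A
  voxel-face counting estimator is retained as a cross-check.
* Convexity is solidity: mask voxels over voxels inside the convex hull
  of in-mask voxel centers (hull via an in-package 3D quickhull). This
  avoids the half-voxel shell bias of corner-based hulls; a digitized
  convex shape scores ≈ 1.
* Eccentricity uses principal axes of the voxel-center covariance, with
  each voxel contributing its own second moment ($s^2/12$ per axis),
  which floors axis lengths for planar or single-voxel masks.

Intensity features: first-order moments of raw in-mask SUVs (mean, SD,
min, max, median, range, skewness, excess kurtosis, energy), intensity
entropy on the discretized-level histogram, and the IVH families at
cut-points 10/25/50/75/90. $V_x$ uses the relative-intensity axis
(threshold $= SUV_{min} + x\% \cdot \text{range}$); $I_x$ is the lowest
SUV among the hottest $x\%$ of the volume. Note $I_x$ is therefore
*non-increasing* in $x$: the worked example (values $1..100$, one voxel
each) gives $I_{90} = 11$ but $I_{50} = 51$. A published invariant
stating the opposite direction contradicts its own worked example; the
math wins here. Constant ROIs return 0 for sd-normalized moments with a
warning.

## Agreement statistics

For each feature and variant pair $(m, n)$, per-case signed percentage
differences
$$d_i = \frac{f_m - f_n}{(f_m + f_n)/2}\times 100\%$$
are summarized by $|\bar d|$ (absolute value of the mean *signed*
difference — the Bland–Altman limits need the signed mean, so the
signed-first reading of the ambiguous notation is used), their SD, and
the reproducibility limits $URL = \bar d + 1.96\,SD$,
$LRL = \bar d - 1.96\,SD$. A case with $f_m = f_n = 0$ counts as perfect
agreement ($d = 0$); only $f_m = -f_n \neq 0$ is excluded (per feature,
never per cohort), with the count logged.

Classification: a feature is *reproducible* iff $|\bar d| \le 25\%$ and
$SD \le 35\%$; passing features are banded by
$m = \max(|URL|, |LRL|)$ — High ($m \le 30$), Intermediate
($30 < m \le 45$), Low ($45 < m \le 50$), otherwise NR. Edges are
inclusive as printed. The nominal High band has a $\pm 1\%$ lower edge;
limits tighter than that ($m < 1$) are graded High — an even tighter
limit is better agreement, not a different class.

Reliability uses the two-way random-effects, absolute-agreement,
single-measurement ICC — ICC(A,1) — treating variant levels as raters.
The model is not stated in the source design; ICC(A,1) is the standard
choice for method-agreement data (systematic offsets between variants
must count against agreement). The 95% CI is the McGraw–Wong
F-distribution interval, verified against an independent reference
implementation, and *precision* is the CI half-width × 100. Published
reliability tables print the column pair "UCI, LCI" with values running
low-then-high; bounds are ordered numerically before use. One printed
row (the reconstruction-table second-order mean) is internally
inconsistent — its bounds give ±7.5, not the printed ±6.5 — and the
acceptance test documents that row rather than matching it.

Inter-item correlations (Pearson, across cases, reference level vs each
other level) justify the reference gray-level choice.

## The phantom: what it emulates, and what a green test means

One case is: a flat background (SUV 1) plus a spherical tumor
(radius 20 mm, mean SUV 8) on a $64\times64\times48$ grid with
$5.49\times5.49\times3.30$ mm voxels, mirroring a clinical PET grid.
Intratumoral heterogeneity is Gaussian white noise smoothed to an 8 mm
correlation length and scaled to 1.5 SUV standard deviation — a single
knob that drives GLCM/GLSZM behavior. Background SUV ~1 and tumor mean
SUV ~8 with moderate heterogeneity are typical of FDG-avid cervical
tumors; the correlation length sits between voxel size and tumor radius
so texture is neither pure noise nor a flat gradient.

* **Mask variants** perturb an implicit surface: the smoothed mask
  indicator (a monotone proxy of the signed distance near the boundary;
  chosen over an exact distance transform for speed — near the boundary,
  where thresholding acts, the two agree up to a smooth monotone map) is
  shifted by a smooth random field calibrated to a boundary displacement
  in mm (defaults: 1.0 / 2.0 / 1.5 mm for MTV1 / MTV2 / GBSV — the
  magnitudes are free parameters, as observer variation is characterized
  only by a Dice floor). Variants failing Dice ≥ 0.75 are regenerated
  with halved jitter, logged.
* **Reconstruction variants** convolve the reference with a Gaussian
  (FWHM 0/4/6/8 mm) and add noise (SD 0/0.05/0.10/0.20 SUV); the
  3DRP-like profile deliberately carries the largest noise so it is the
  most divergent variant, matching its empirically lowest
  reproducibility. OSEM is the exact identity.

The phantom reproduces the *statistical shape* of the analysis — paired
variants, Dice-filtered cohorts, heterogeneity-driven texture — not PET
physics: no attenuation, scatter, partial volume, or tomographic
projection. A green pipeline run therefore establishes that the
extraction and agreement machinery behaves correctly and reproduces the
qualitative trends (gray-level pair 64-128 more reproducible than
64-256; 3DRP-like variant most divergent), **not** that clinical
per-feature values are reproduced: cohort-dependent numbers depend on
undeposited patient scans.

## Determinism and degenerate inputs

Every random step takes an explicit seed; a case bundle is a pure
function of (spec, seed), and `.Random.seed` is saved/restored so the
caller's RNG stream is untouched. Known degenerate inputs and their
documented behavior: constant ROI (level 1 everywhere, coarseness
sentinel, zero entropies, ID = IDM = 1), single-voxel ROI (GLCM
undefined → error), empty masks (error), zero between-case variance
(ICC `NA` sentinel with warning), planar masks (eccentricity floored by
the voxel moment).

## Limitations

* Texture values at $N_g = 256$ on small ROIs are sparse-matrix
  statistics; they are computed faithfully but are intrinsically noisy —
  which is precisely the sensitivity the gray-level study measures.
* The feature catalogue beyond the named members is a convention;
  absolute values of convention-dependent features (e.g. run-percentage
  normalization) are only comparable within this package.
* Sphericity is ≤ 1 for continuum shapes, but on coarsely digitized
  near-spheres (radius of a few voxels) the mesh area estimator can
  push it a few percent above 1; it is reported unclamped because the
  agreement statistics need the estimator's actual value, not a
  truncated one.
* The phantom's observer model is isotropic boundary jitter; real
  observers disagree systematically (e.g. at organ interfaces), which
  the Dice floor captures only crudely.
* I/O supports NIfTI-1 and NRRD scalar 3D images only; DICOM assembly
  and SUV conversion from raw counts are out of scope.
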