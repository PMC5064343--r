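---
title: "Partial volume correction and SUVR quantification for amyloid PET: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial volume correction and SUVR quantification for amyloid PET: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amypvc)
```

## The problem

Amyloid PET with tracers such as ^11^C-PiB measures fibrillar amyloid-beta
load in cortical gray matter (GM). Two properties of PET degrade that
measurement. First, the scanner's finite resolution — modeled here as a 3D
Gaussian point spread function (PSF) — mixes signal between neighboring
structures (spill-in and spill-out). Second, a voxel at a tissue boundary
averages the uptake of the tissues it straddles (the tissue-fraction
effect). Together these constitute the partial volume effect (PVE), and in
amyloid imaging they bias cortical uptake *downward*, because the cortical
ribbon is thin relative to the PSF and its neighbors (CSF, and
white matter with only nonspecific tracer retention) pull the measured
value away from the true GM concentration. Partial volume correction (PVC)
compensates computationally.

`amypvc` implements a probability-map-based PVC in which the anatomical
information comes from tissue probability maps segmented externally from a
structural scan — CT acquired in the same sitting on a PET/CT scanner, or
MRI — followed by standard uptake value ratio (SUVR) imaging against an
eroded cerebellar reference, a cross-modality scale (α) correction, and
the group statistics used to compare two modalities' SUVR images. All
inputs must already share one voxel grid; registration and segmentation
are upstream, out-of-scope steps.

## Resolution matching

PVC divides the PET image by tissue probability, so the probability maps
must first be degraded to the PET image's resolution. The bookkeeping
lives in `SmoothingSpec`: the PET scanner PSF SD (default 4.0 mm), the SD
of the Gaussian filter applied when the PET image was created (default
5.0 mm), and the structural image PSF SD (default 1.0 mm, a CT-like
value). Under the default **additive** rule the effective PET PSF SD is

$$\sigma_\text{PET} = 4.0 + 5.0 = 9.0\ \text{mm},$$

and the kernel applied to the probability maps is

$$\sigma_\text{match} = \sigma_\text{PET} - \sigma_\text{struct} = 9.0 - 1.0 = 8.0\ \text{mm}.$$

The additive rule is the protocol's stated convention and is therefore the
default. It is worth flagging that the composition law of Gaussian
convolution actually combines SDs in quadrature,
$\sigma = \sqrt{\sigma_1^2 + \sigma_2^2}$; the package offers
`rule = "quadrature"` for users who prefer the physically standard
arithmetic, and it never substitutes one rule for the other silently.
With the default inputs the two rules differ by ~2.6 mm in
$\sigma_\text{PET}$, so the choice is consequential and is recorded in
every run report.

```{r}
spec <- SmoothingSpec()           # 4.0, 5.0, 1.0 mm, additive
combinedPetSd(spec)
matchingKernelSd(spec)
matchingKernelSd(SmoothingSpec(rule = "quadrature"))
```

Smoothing itself (`gaussianSmooth`) is separable Gaussian convolution with
per-axis SD in voxels = SD in mm / spacing, kernel truncated at 4 SD
(mass loss < 1e-4) and normalized. Outside the grid the volume is extended
with zeros: outside the head there is no tissue, which is the correct
reading for probability maps. A consequence worth knowing is that values
within ~4 SD of the grid border shrink toward zero; every quantitative
guarantee in the test suite is therefore stated for voxels at least 4 SD
from the border, and the phantom generator enforces that margin around its
geometry.

## The correction

Given the PET image $P$, smoothed WM map $W_s$ and smoothed GM map $G_s$,
`runPvc` executes:

1. **WM mask**: voxels with $W_s \ge 0.95$ (inclusive threshold).
2. **WM reference**: the **median** of $P$ over that mask — the median is
   robust to outliers; the historical alternative (the maximum) is
   available as `wmStatistic = "max"`.
3. **Bias subtraction**: $P'(v) = P(v) - \text{wmRef} \cdot W_s(v)$. The
   product models nonspecific WM retention spread by the PSF.
4. **GM division**: $\text{PVC}(v) = P'(v) / G_s(v)$, computed only inside
   the **GM mask** $G_s \ge 0.35$; everything outside is excluded.

Excluded voxels are stored as `NaN` (0 would be a legal uptake value, so a
sentinel outside the value range is the unambiguous choice; `writeVolume`
can substitute 0 for viewers that cannot render NaN). The 0.35 floor on
in-mask divisors bounds the division, so no blow-ups can occur. Voxels
that go negative after subtraction are **kept** by default — they carry
noise information into subsequent statistics and no policy is prescribed
by the protocol — with `negativePolicy = "clip_to_zero"` available.

Two exact properties anchor the implementation and are enforced in the
tests: the correction is homogeneous of degree 1 (scaling PET by $c$
scales PVC-PET by $c$, since the WM reference scales along), and on a
noiseless volume synthesized as $a_G G_s + a_W W_s$ with deep-WM voxels
($W_s \ge 0.95$, $G_s = 0$) present, the in-mask output equals $a_G$ to
machine precision.

## SUVR with an eroded cerebellar reference

The cerebellar cortex carries essentially no specific PiB binding and
serves as the reference tissue. Because the periphery of an atlas region
is unreliable (folia, boundary effects), the reference VOI is restricted
to its central core: `erodeToHalf` applies one-voxel binary erosion steps
(26-connectivity 3×3×3 box by default; 6 and 18 available) until the
voxel count first drops to at most half the original. "Exactly half" is
generally unattainable on a discrete grid, so the stop rule is the first
count ≤ half — simple and monotone. If a step would empty the mask before
reaching half (very small or thin VOIs), the last nonempty mask is
returned with a warning. Erosion counts voxels, not mm: with anisotropic
voxels the removed rind is geometrically thinner along finer axes.

`computeSuvr` takes the median of the PVC-PET image over the non-excluded
voxels of the eroded reference VOI and divides the whole image by it. By
construction the median SUVR over that VOI is exactly 1, and the SUVR
image is invariant to any global rescaling of its input. The same
erosion is applied to each assessment VOI before regional statistics.

## Cross-modality α correction and statistics

When the same subjects have SUVR images from two structural modalities
(CT-based and MRI-based PVC), the two scales differ by a roughly constant
factor, because CT's lower soft-tissue contrast yields systematically
wider GM segmentations. The workflow is: for each assessment VOI, an
ordinary least-squares regression (with intercept — the observed relation
is a line, not a proportionality; a through-origin variant exists for
sensitivity analysis) of one modality's voxel SUVR on the other's, pooling
voxels across subjects; α is the arithmetic mean of the per-VOI slopes
(`poolAlpha`), applied by plain multiplication (`applyAlpha`).

Group comparisons mirror the protocol's two tests:

- `voxelwiseTTest`: per-voxel two-sample (pooled variance) or paired t
  statistic, two-sided p from the t distribution, thresholded at p < .001
  **uncorrected** — no multiple-testing correction is applied and the
  output says so. The design matrix of the original GLM analysis is not
  fully specified upstream, so both paired and two-sample modes are
  provided and neither is asserted as canonical; paired is the natural
  default for same-subject modality comparisons. Voxels with zero
  within-group variance are marked non-evaluable (NaN) rather than
  infinitely significant, and any voxel excluded in any image is skipped.
- `mannWhitneyU`: two-sided Mann–Whitney U per VOI at p < .005, exact by
  the permutation distribution when both groups have ≤ 8 observations
  and no ties, otherwise the normal approximation with tie-corrected
  variance and continuity correction. The continuity-corrected
  approximation agrees with exact enumeration to within 0.005 wherever
  the exact p ≤ 0.1 and within 0.0125 everywhere (worst at the center of
  the U distribution); the test suite checks this exhaustively at
  n = m = 7. Pooling voxels per VOI per group follows the original
  analysis; voxels within a subject are not independent, so a
  subject-level summary (e.g. feeding per-subject medians) is the
  statistically cleaner alternative and the function accepts any numeric
  vectors.
- `voiDistribution`: quartiles by the linear-interpolation convention
  (R's type 7), fixed so reported boxplot numbers are reproducible.

## The digital phantom

`PhantomSpec` / `generateTissueMaps` / `simulatePet` build a synthetic
head with known ground truth: a nested-ellipsoid cerebrum (CSF envelope,
GM shell, WM core) and a compact cerebellar ellipsoid pair, probability
maps that ramp 0→1 over a configurable boundary softness (1 mm by
default, emulating segmentation softness), a PET image formed as
$a_G \cdot GM + a_W \cdot WM$ (with the cerebellar GM uptake $a_\text{ref}$
substituted inside the reference label), blurred by the PSF and degraded
with additive Gaussian noise. `generateCase("AD")` sets
$a_G = 2 a_\text{ref}$ (true cortical SUVR 2.0); `"NL"` sets
$a_G = a_\text{ref}$ (true SUVR 1.0); nonspecific WM uptake is 1.5 in
both, making WM the brightest tissue of the NL case as in real control
scans. Noise SD 0.05 activity units (5% of the reference uptake) is a
representative post-reconstruction noise level for an averaged late-frame
acquisition.

The default geometry was chosen once, for compatibility with the method's
own smoothing, and is deliberately *not* thin-cortex realistic: the GM
shell is 14 mm thick and the cerebellum is a compact structure with a
small WM core, so that (a) deep-WM voxels survive the 0.95 threshold
after an 8–9 mm blur, (b) the eroded cerebellar VOI retains smoothed GM
probability above the 0.35 mask floor, and (c) the reference region is
well recovered by the PSF, as a real (large) cerebellum is. With an
anatomically thin cortex the 0.95/0.35 thresholds of the protocol are
unsatisfiable after an 8 mm blur on a phantom of this size — an
instructive reminder that those thresholds encode assumptions about real
brain geometry. A coarser second modality can be emulated with
`degradeMaps` (extra blur + clamped jitter), and
`simulateSuvrPairs` draws per-VOI paired voxel samples with a known
inter-modality slope for rehearsing the α workflow.

What passing phantom tests do **not** show: performance on real scans
with segmentation errors, misregistration, non-Gaussian and spatially
varying PSFs, atrophied thin cortex, or correlated reconstruction noise.
The phantom validates the arithmetic and the contracts, not clinical
accuracy.

## Numerical choices and degenerate inputs

- Thresholds compare with ≥, so an all-ones map satisfies the 0.95 mask.
- Medians over an even count take the midpoint of the two central order
  statistics.
- Grid compatibility: shapes must match exactly; affines elementwise
  within 1e-4 (`assertSameGrid`, applied at the entry of every
  multi-volume operation). No resampling is ever attempted.
- Empty WM mask, empty GM mask, a reference VOI entirely excluded, or a
  non-positive reference value are hard errors with messages naming the
  probable upstream cause.
- An erosion that would empty a mask warns and returns the last nonempty
  stage; a single-voxel mask is returned as-is with a warning.
- Problem sizes in the validation suite: the full-size phantom is a 96³
  grid of 2 mm voxels; the test suite uses a proportionally reduced 48³
  grid of 3 mm voxels with a 6 mm PSF, which preserves every ratio that
  matters (shell thickness vs PSF, margin vs truncation radius) while
  keeping each end-to-end run under a few seconds.

## Known limitations

- The two-compartment model (GM + WM) ignores CSF partial volume beyond
  what the GM division absorbs, and region-based (GTM-style) corrections
  are out of scope.
- The additive SD default reproduces the protocol's arithmetic, not
  convolution physics; users matching independently measured PSFs should
  use the quadrature rule.
- Erosion in voxel units makes eroded VOIs spacing-dependent; label
  volumes resampled from another grid should be regenerated, not reused.
- Pooled-voxel Mann–Whitney p-values overstate evidence when voxels
  within subjects are correlated; prefer subject-level summaries for
  inference.
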