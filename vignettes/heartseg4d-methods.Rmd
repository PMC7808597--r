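---
title: "Atlas-based whole-heart segmentation for 4D-CT: models and methods"
author: "heartseg4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based whole-heart segmentation for 4D-CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartseg4d)
```

## The problem

Incidental cardiac dose during lung radiotherapy is associated with
radiation-induced heart disease, and the heart moves with respiration —
excursions up to roughly 13 mm have been reported. Respiratory-binned 4D-CT
(ten volumes at 0%–90% of the breathing cycle) captures that motion, but
manually contouring the heart on every phase is too slow for routine care
and subject to inter-observer variability. `heartseg4d` implements a fully
automatic alternative: multi-atlas segmentation of the whole heart on the
end-exhale (0%) phase, deformable propagation of that delineation to the
other nine phases, and construction of a motion-encompassing planning
organ-at-risk volume (PRV) as the union of the per-phase delineations.

## Pipeline

For a target patient and an atlas set (previously delineated image–mask
pairs):

1. **Crop.** The lungs are segmented by thresholding (default −320 HU),
   discarding components that touch the lateral image borders (exterior
   air) or are smaller than 50 cm³, and keeping the largest one or two.
   The volume of interest is the lung bounding box expanded by a 10 mm
   margin; the heart sits in the mediastinum between the lungs, so the box
   contains it. All subsequent work happens on this crop.
2. **Register.** Each atlas is aligned to the target with a two-step
   process: multi-resolution rigid registration under a mean-squared
   intensity difference metric, then Thirion demons deformable
   registration initialized with the rigid result.
3. **Select.** Warped atlas masks are compared to a voxelwise majority
   consensus; atlases whose mean absolute surface distance (MASD) to the
   consensus exceeds `median + 1.5 · IQR` are rejected as discordant. At
   least three atlases are always retained.
4. **Fuse.** Local-weighted label fusion: each retained atlas votes with
   per-voxel weight `1 / (ε + local mean |ΔHU|)` over a 5 mm cubic patch,
   and the weighted vote is thresholded at 0.5 to give the automatic heart
   mask.
5. **Propagate.** The 0%-phase mask is carried to each remaining phase by
   an intra-patient demons registration (no rigid step — same scanner
   frame; identity initialization). Registration is star-shaped, 0% → k
   directly for every phase k, rather than chained phase-to-phase, which
   avoids accumulating registration error across the cycle.
6. **PRV.** The union of the ten per-phase masks, on the 0% grid.

The alternative `independent` mode replaces step 5 by a full multi-atlas
segmentation of every phase; it costs ten fusions instead of one fusion
plus nine cheap intra-patient registrations, and the package exposes both
so their agreement can be measured.

## Registration details

**Conventions.** Transforms map fixed-space physical points into moving
space (the resampling convention): applying a transform `T` to a moving
image produces `I∘T` on the fixed grid. Consequently, registering a moving
image that was constructed by resampling the fixed image through a known
transform `S` recovers `S⁻¹`. A worked example: if the moving image content
sits 4 mm to the left of the fixed content, the recovered translation is
+4 mm along x — the sampling point must move right to fetch it.

**Rigid step.** Six parameters (Euler angles, translation) minimize the
mean squared intensity difference by Nelder–Mead with restarts over a
three-level pyramid (shrink 4, 2, 1). The full-resolution level is needed
for sub-voxel accuracy — the coarse-level metric minimum is measurably
biased (up to ~0.4 mm / 1.7° on the phantom) — and evaluates the metric on
every second voxel per axis, which preserves the full-resolution minimum at
an eighth of the cost. Mild smoothing (0.7 voxel) at that level suppresses
the interpolation asymmetry between a sharp fixed image and a resampled
moving image. The initial translation aligns the intensity centers of mass
(voxels above −400 HU).

**Demons step.** The classic Thirion update with the fixed-image gradient,

\[ \delta u(v) = \frac{(f - m)\,\nabla f}{\lVert\nabla f\rVert^2 + (f-m)^2}, \]

capped at 2 mm per iteration, zero where the denominator falls below
1e−9. Regularization is diffusion-like: the accumulated field is smoothed
with a 2 mm Gaussian after every iteration (an update-field "fluid"
smoothing is also available via `update_sigma_mm`, off by default). The
pyramid is shrink 4/2/1 with 300/150/100 iterations and pyramid
pre-smoothing of 3/2/1.5 voxels.

Two of these choices deserve their rationale:

* *Diffusion smoothing with many iterations.* Most of the heart surface in
  the mediastinum has almost no intensity contrast; the informative signal
  lives at the heart–lung interfaces and the diaphragm. Smoothing the
  accumulated field lets the displacement measured at those interfaces
  diffuse into the low-contrast interior, converging towards a harmonic
  interpolation of the boundary motion. With few iterations that diffusion
  never reaches the interior — iteration counts here are chosen so a 10 mm
  bulk displacement of a ~50 mm structure is recovered.
* *Generous pyramid pre-smoothing.* The heart/soft-tissue contrast (5 HU in
  the phantom) is below the noise floor (10 HU) voxelwise, but smoothing
  with 1.5 voxels at full resolution suppresses the noise faster than the
  edge, making the weak boundary usable by the demons forces.

Masks are warped as float occupancies with linear interpolation and
thresholded at 0.5, which produces smoother propagated contours than
nearest-neighbour warping.

## Evaluation metrics

Delineations are compared with the Dice similarity coefficient
(`2|A∩B| / (|A|+|B|)`), the mean absolute surface-to-surface distance, and
the Hausdorff distance (maximum surface-to-surface distance). A surface is
realized as the set of centers of foreground voxels with a six-connected
background neighbour — deterministic and directly checkable against
exhaustive oracles, unlike mesh extraction. MASD symmetrizes as the average
of the two directed means (the pooled-point alternative differs by less
than the voxel scale but is not identical; the choice is stated here
because conventions vary). Distances are computed by an exact anisotropic
Euclidean distance transform of the target surface sampled at the source
surface voxels; the test suite checks this against an exhaustive pairwise
oracle to 1e−9. Cohort tables report mean ± sample standard deviation
(n−1; a single observation reports 0) per phase, a pooled all-phases row,
and a PRV row.

## The phantom cohort

No clinical 4D-CT data ship with the package; a parametric thorax phantom
stands in for them. Its geometry is an elliptic-cylinder body in air, two
lung ellipsoids, and a heart ellipsoid seated between them:

* The heart ellipsoid overlaps the medial lung surfaces, so part of the
  heart boundary is a high-contrast heart–lung interface while the rest
  borders soft tissue at 45 vs 40 HU — deliberately below the 10 HU noise,
  reproducing the low-contrast mediastinum that makes automatic heart
  delineation genuinely hard.
* Default grid: 64³ voxels at 2.5 mm isotropic. Clinical scans (1.5 mm
  slices) are finer; a desk-scale grid keeps cohort experiments tractable
  while preserving the mm-scale physics of every algorithm (all parameters
  are in mm, not voxels). The clinical in-plane resolution is not
  reproduced — the source acquisitions do not pin it down, and the phantom
  makes no claim to the clinical grid.
* Respiration: phase `p` of `n` displaces the heart by
  `A(1−cos 2πp/n)/2` inferiorly plus a 0.3 fraction anteriorly, and lowers
  the lung floors (diaphragm) identically with the apices fixed. Phase 0 is
  end-exhale; 4D-CT phase-binning conventions differ on whether 0% means
  end-inhale or end-exhale, so the package fixes end-exhale and documents
  it. Default amplitude 10 mm, within the reported ≤13 mm envelope. Phases
  are regenerated analytically, so per-phase truth masks are exact and
  phase 0 equals the base phantom bit-for-bit.
* Cohorts perturb radii (×(1+N(0,σ)) per axis), centers (±N(0, σ·mean
  radius)) and heart orientation with fractional variation σ = 0.08 by
  default — an engineering choice, since no quantitative inter-patient
  variability is available to emulate; draws violating the anatomy
  invariants (heart outside the body, lungs touching the body surface,
  heart escaping the lung bounding box) are redrawn.

What the phantom does *not* emulate: cardiac-cycle motion (the clinical
4D-CT it mimics lacks cardiac gating), imaging artefacts, intensity
inhomogeneity, and real anatomical shape variability beyond affine-like
perturbation of ellipsoids. Passing the cohort experiments therefore shows
the pipeline's machinery is correct and robust under controlled,
realistic-contrast conditions; it does not certify clinical accuracy.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based and boxes half-open `[lo, hi)`; physical
  coordinates follow the NIfTI/ITK convention
  `point = origin + direction · (index ∘ spacing)`.
* Out-of-support resampling fills −1000 HU (air) for images and 0 for
  masks, keeping registration stable near crop borders.
* Consensus voting uses strictly-greater-than-half (ties excluded); the
  fusion threshold uses ≥ 0.5 (ties included). Both are deterministic and
  stated.
* An empty warped atlas mask receives an infinite deviation score, making
  it a guaranteed rejection candidate; a registration failure drops that
  atlas with a logged message instead of aborting, as long as three
  atlases survive.
* Masks are stored as unsigned 8-bit in NIfTI/MetaImage; mask reading
  binarizes nonzero values.

## Problem sizes used by the shipped experiments

The package's own validation runs at the defaults above: a 10-member
cohort for the leave-one-out experiment, one ten-phase study for the 4D
propagation experiment, and a 4-member ten-phase cohort for the
propagate-vs-independent comparison (the smallest cohort a leave-one-out
design admits, chosen because the independent arm performs ten fusions per
member). Unit tests use a 48³ phantom at the same 160 mm physical extent.

## A worked example

```{r example, eval = FALSE}
library(heartseg4d)

cohort <- make_cohort(10, seed = 1)
loo <- run_leave_one_out(cohort, pipeline_config())
print(loo$table, digits = 3)

study <- make_4d_study(cohort[[1]], motion_spec(amplitude_mm = 10))
res <- run_single(study, cohort[2:5], pipeline_config())
print(res$results, digits = 3)
```

## Known limitations

* The demons implementation is the classic asymmetric Thirion scheme;
  symmetric/diffeomorphic variants are not provided, and invertibility is
  only monitored (Jacobian-determinant check), not enforced.
* Rigid registration assumes same-modality CT (mean squared difference);
  there is no mutual-information option.
* The atlas rejection rule (median + 1.5·IQR fence on MASD-to-consensus)
  and the inverse-mean-absolute-difference weighting are canonical but not
  the only choices; both are exposed in `fusion_config()`.
* DICOM series reading and dose/DVH computation are out of scope; images
  enter as NIfTI or MetaImage volumes.
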