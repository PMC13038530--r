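---
title: "Prior information-based subtraction radiography: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior information-based subtraction radiography: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pibsim)
```

## The problem and the method

On a treatment-room X-ray of the thorax, the lung tumor competes with the
projected signal of every structure along the ray. Bone is the worst
offender: at some gantry angles the tumor projects onto the vertebral
column and is invisible. The idea implemented here is to use the planning
CT — acquired before treatment and already rigidly alignable to the patient
via the routine couch correction — as *prior information*: everything
outside the thoracic cavity (chest wall, spine, sternum; the
"non-essential" or NE tissues for lung imaging) is stable over a course of
treatment, so its radiographic signal can be simulated from the planning CT
and subtracted from the treatment-day image.

In the line-integral (optical depth) domain the subtraction is exact by
linearity of the ray transform: if the NE tissues occupy the same positions
in both volumes, the treatment-day projection minus the NE projection
equals the projection of the cavity contents alone. This identity is the
method's central correctness property and the package tests it literally
(oracle-aligned pipeline versus a direct projection of the
cavity-contents-only volume, at machine precision).

The pipeline (`run_pipeline()`) follows the clinical workflow: cavity
segmentation on the planning CT, CT-number override of the cavity to
−1024 HU (`ne_planning_ct()`), rigid registration of one treatment-day
volume to the planning CT, application of that single transform to *all*
respiratory states (couch corrections are not re-estimated per breath),
resampling onto the planning grid, projection, and pixelwise subtraction.

## Coordinate and geometry conventions

One convention is fixed and asserted in tests rather than made
configurable:

* patient axes are LPS-style — +x patient-left, +y posterior, +z superior —
  with a supine patient;
* rigid transforms use intrinsic Z–Y–X rotations (degrees) about the
  isocenter followed by a translation (mm);
* gantry angle 0° puts the source anterior of the patient, increasing
  toward patient-left; the detector u axis lies in the axial plane and v
  runs inferior, so image row 1 is superior;
* voxel `(i, j, k)` (1-based) is centered at `origin + (i-1, j-1, k-1) *
  spacing`.

The default projection geometry is 100 cm source-to-axis and 150 cm
source-to-imager distance. The default detector is 256×256 pixels at
1.668 mm pitch — an exact 4× binning of a 1024² detector at 0.417 mm —
which keeps the full bench fast on one CPU; the full-resolution detector is
one `projection_geometry()` call away.

## The synthetic study

`make_study()` builds the whole experiment: a planning CT with the tumor at
its most inferior position (end of inhalation), labels, and one
treatment-day CT per respiratory state, each the same phantom with the
tumor displaced superiorly (default 0, 10, 20 mm — superior/inferior motion
only, the dominant clinical component) and the whole phantom moved by one
six-dimensional setup error (default (8, −5, 12) mm and (1, −1, 2)°, a
plausible initial setup error; magnitudes of this kind are not prescribed
by the emulated protocol, so they are package defaults, stated here once).

The phantom itself (`phantom_spec()`) is an anthropomorphic abstraction:

* an elliptic-cylinder body of water-equivalent material (0 HU, semi-axes
  150×95 mm), in air at −1024 HU;
* two lung-equivalent elliptic cylinders at −700 HU (semi-axes 50×65 mm;
  the chest wall stays ≥ ~10 mm thick everywhere so the lungs are properly
  enclosed — a requirement of threshold-based cavity segmentation);
* a 15 mm-radius solid tumor sphere at +20 HU inside the right lung, placed
  at (−50, −27) mm so that at gantry 150° it projects onto the vertebral
  column — the most challenging angle for conventional imaging;
* a bone set at +600 HU: a posterior midline chain of vertebral-body
  cylinders (radius 12 mm, height 20 mm, 25 mm spacing) with small lateral
  transverse-process spheres, plus an anterior sternum rod. The processes
  and sternum are deliberate: a bare cylinder chain is rotationally
  symmetric about its own axis, so bone-driven registration could not
  observe one rotational degree of freedom; anterior bone far from the
  spine (as in real patients) makes the rotate-plus-compensating-translate
  mode visible.

Voxelization is analytic: each voxel takes the HU of the material
containing its center, and treatment-day volumes are produced by
transforming the *shapes* before voxelization. This keeps interpolation
error out of the ground truth — registration accuracy and subtraction
exactness can be attributed correctly. The cost is crisp, partial-volume-free
edges that real CTs do not have; optional Gaussian smoothing
(`smooth_gaussian()`) and HU noise (`noise_sd`, default 0) are available as
realism dials but all defaults keep them off, so the stated accuracies are
for the clean case. What the phantom does *not* emulate: CT physics (beam
hardening, scanner noise texture, iterative-reconstruction artifacts),
ribs, diaphragm or heart anatomy, deformable respiratory motion, or the 1D
surrogate signal of a physical motion stage. Passing tests therefore
demonstrate the mechanics of the method, not its performance on patient
data.

The default grid is 160×128×120 voxels at 2.5 mm (400×320×300 mm) — a
desk-scale stand-in for a clinical 50 cm field of view at 2 mm slices.
These are also the problem sizes used throughout the test suite and the
acceptance script; everything scales to finer grids through the same
interfaces.

## Projection

`project()` computes exact voxel-intersection path lengths (Siddon-style
incremental traversal) from the source through every detector pixel center.
There is no detector blur, scatter, or spectral model; a seeded Poisson
noise dial (`add_poisson_noise()`) exists for robustness experiments. The
projector is linear in the attenuation volume to machine precision — the
property that makes subtraction exact.

`project_oracle()` is an independent check, not a production path: dense
fixed-step midpoint sampling with trilinear interpolation. Two details
matter when comparing the two. First, the trilinear interpolant is clamped
over the half-voxel border so both integrators see the same piecewise
volume support. Second, the two integrate *different models* of the same
grid (piecewise-constant versus trilinear), which agree only for fields
that are smooth relative to the voxel; the equivalence tests therefore use
random sums of broad Gaussian blobs (σ of 16–24 voxels, well inside the
grid). On crisp fields the projected image of the voxel model is a
staircase with steps of one voxel × magnification — visible in tests that
try to shift a phantom by a sub-voxel amount and in the translation-
equivariance fixture, which uses fine (0.8 mm) voxels for exactly this
reason.

HU→μ conversion is the single-energy linear ramp
`μ = μ_water (1 + HU/1000)`, zero at and below −1000 HU (so the −1024 HU
override removes all signal), with `μ_water = 0.019 mm⁻¹`, approximately
water at the effective energy of a 120 kVp beam. Only relative contrast
matters for subtraction, so the constant is configurable and nothing
downstream depends on its absolute value.

Display mapping (`to_display()`) is `D = 1 − exp(−L)` (exponential mapping
with intensity inversion, air dark). Per-image min/max rescaling is the
default for viewing; the pipeline's display-domain subtraction mode uses
the *unrescaled* mapping so that minuend and subtrahend share one scale.
Whether subtraction happens before or after the exponential mapping is an
open choice in the emulated workflow; both modes are provided
(`domain = "line_integral"` is the default because the additive identity
holds there, `domain = "display"` reproduces subtraction of viewer-mapped
images; the difference is bookkept in each image's provenance).

## Registration

Alignment is "based on bony structures" made literal: both volumes pass
through `bone_emphasis()` (soft threshold `max(HU − 150, 0)`), and 3D/3D
registration maximizes normalized cross-correlation of the emphasized
volumes over the six rigid parameters. The metric is evaluated only on the
dilated support of the fixed bone (plus 2 voxels), over a mean-pooled
pyramid (factors 4, 2, 1), with a derivative-free coordinate search per
level (repeated stepping in improving directions, step halving on stall,
fixed iteration cap). Translation is initialized from the bone-weighted
centroids. Everything is deterministic: no random restarts, no seeds.
Defaults: bone threshold 150 HU (above soft tissue at ~0–100 HU, far below
bone at 600 HU), NCC convergence floor 0.2, translation/rotation
tolerances 0.05 mm / 0.02°.

2D/2D registration emulates systems with only planar imaging: per view
(45° and 135°), the in-plane shift maximizing the cross-correlation of
bone-emphasized projections (FFT-based, quadratic sub-pixel peak), detector
shifts divided by the SID/SAD magnification, and the two per-view 2D shifts
combined by least squares into a 3D translation. Rotations are fixed at
zero by design — couch corrections are classically translational, and
recovering rotations from two static views is out of scope.

Known limits, measured on the default study: recovery of random setup
errors (|t| ≤ 20 mm, |r| ≤ 3°) succeeds to sub-voxel/sub-half-degree
accuracy (the acceptance script reports the success rate and median
errors); because the phantom's thin bones are mostly boundary voxels,
the *HU residual* after alignment is dominated by trilinear resampling
blur against the crisp planning volume (~tens of HU on average over bone
voxels even at the true transform), not by registration error.

## Subtraction residuals on a crisp phantom

The same resampling-versus-crisp mismatch bounds what estimated-alignment
subtraction can achieve outside the cavity: rays grazing material
boundaries (body silhouette, bone limbs, lung walls) keep residuals whose
upper tail is comparable to the tumor signal, even with a perfect
transform. These residuals sit at anatomy boundaries, away from the tumor,
and demonstrably do not impair localization or tracking (tested); the
package documents rather than hides them — the tests assert that the
*median* outside-cavity background is far below the tumor signal and that
tracking and localization are unaffected. On smoother, more realistic
volumes the residuals shrink with the edge gradients. In oracle-alignment
mode (ground-truth transform, analytic regeneration of the aligned
volumes) the subtraction identity holds to machine precision, which is how
subtraction correctness is tested independently of registration and
interpolation.

## Evaluation

CNR uses ROIs derived from simulation ground truth — the projected tumor
disc, and a background annulus at 1.5–2.5 projected radii restricted to
the projected body — removing the ROI-placement subjectivity that makes
manual CNR evaluation fragile. One honest caveat, measured on this bench:
where the tumor ROI sits on a steep thickness gradient of the body, the
NE signal difference between disc and annulus can exceed the true tumor
contrast, inflating the *conventional* image's "CNR" with background
structure rather than visibility. At one of the twelve standard angles
this makes the conventional CNR exceed the PIBS CNR even though the tumor
is plainly better separated on the PIBS image; the per-angle CNR table in
`evaluation_report()` exposes this rather than averaging it away.

Tumor localization is matched filtering with the projected-sphere
chord-length template. Affine trends (constant plus in-plane ramps) are
projected out of both template and patch before correlating — the cavity
background carries smooth chord-length gradients that otherwise bias the
peak by more than a pixel — and the peak is refined by quadratic
interpolation. The reported *confidence* is deliberately the plain
mean-removed NCC at the winning position, without the nuisance regressors:
match quality should measure how much local variance the disc itself
explains. The default low-confidence floor is 0.7; clean tumor fixes score
≳0.9 while disc-like false matches on vertebral bodies score lower.

Motion traces divide detector displacements by the magnification at the
*planning tumor depth* — prior knowledge the method has by construction —
rather than the nominal SID/SAD. For an off-axis tumor the nominal scale
carries a systematic error of order (depth offset)/SAD, which approaches
the millimeter level for 20 mm shifts; the tumor-depth scale is exact for
superior/inferior motion in axial views. `scale = "nominal"` restores the
simpler convention.

## Numerical and degenerate cases

* Rays missing the volume integrate to zero; tangent rays are handled by
  the slab test of the traversal.
* Zero background SD makes CNR undefined; it is reported as a flagged `NA`,
  never infinity.
* A flat image yields a low-confidence localization, not an error; a
  non-converged registration still returns its best transform, flagged.
* Label volumes are resampled nearest-neighbor only.
* Difference (PIBS) images keep negative values — they carry misalignment
  information — and are displayed with a symmetric window about zero;
  their files record a `difference` flag so round-trips skip domain
  validation.
* Gimbal lock in the Z–Y–X Euler decomposition (pitch = ±90°) folds the
  remaining rotation into one angle; setup errors are degrees-scale, far
  from the singularity.

## Reproducibility

Every random draw (study noise, acceptance-script setup errors and test
phantoms) flows from an explicit integer seed; registration and projection
are seed-free and deterministic. Configuration files (YAML/JSON) are
strictly validated — unknown keys are rejected — and every CLI run writes
its fully resolved configuration next to its outputs, so any artifact on
disk is reconstructable from the config and seed alone.
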