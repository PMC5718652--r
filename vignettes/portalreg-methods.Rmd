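---
title: "Methods: portal-DRR registration, tilt correction, and the synthetic phantom study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: portal-DRR registration, tilt correction, and the synthetic phantom study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

External-beam radiotherapy delivers dose through a field planned on a CT
study. Before treatment, a megavoltage portal radiograph is compared with
the planning DRR (digitally reconstructed radiograph) to check that the
patient lies where the plan assumes. Both images carry a burned-in
graticule — the isocenter, orthogonal axes, and a tick every centimeter —
and the clinical question is the beam's-eye-view (BEV) displacement of the
anatomy relative to the planned field, in millimeters.

`portalreg` implements this comparison end to end: a control-point
transform that puts the portal image into the DRR's coordinate frame
(including out-of-plane plate tilt), complementary-color fusion for visual
verification, an automatic offset estimator driven by mutual information,
a synthetic phantom generator, and the statistics used to score estimates
against known truth.

## Geometry: the control-point transform

Three points are designated on each image using the graticule: the
isocenter and one point on each axis, conventionally 10 cm out. The DRR's
points define the beam frame (mm about the isocenter, +x right, +y up);
the portal's points give the corresponding plate-pixel vectors. The linear
part of the portal map is modeled as

    M = b * Rot(theta) * Rot(phi) * St(tilt) * Rot(-phi),
    St(t) = diag(1, 1/cos t)

where `b` is the zoom ratio, `theta` the in-plane rotation about the beam
axis, and the conjugated stretch accounts for a plate tilted by `tilt`
about an in-plane axis at azimuth `phi`: the tilt-axis direction is
imaged at true scale while the normal direction is stretched by `1/cos`.
This is the small-angle (affine) model of an oblique plate; the true
perspective map differs by terms that grow away from the control points.

`solve_linear_map()` determines `M` exactly from the two axis-point pairs;
`decompose_transform()` recovers `(b, theta, phi, tilt)` by the
polar/singular-value factorization: `b` is the smaller singular value,
`cos(tilt)` the singular-value ratio, `phi + 90°` the azimuth of the
stretched right-singular direction, and `theta` the residual rotation.
The closed-form parameter equations this factorization replaces are
algebraically equivalent on the composition contract above, which is the
form we treat as definitive; the factorization is numerically stable and
is property-tested to recompose `M` to below 1e-9 relative error over
1000 random draws. Two gauge conventions apply: `phi` is reported in
(-90°, 90°] (the tilt axis is a line, not a direction), and equal
singular values (no tilt) deterministically report `tilt = 0, phi = 0`.
Orientation-reversing maps (negative determinant) are rejected rather
than silently factorized.

`correct_image()` resamples the portal into the DRR frame by inverse
mapping with bilinear interpolation; output pixels that pull from outside
the portal footprint are flagged in a background mask rather than given a
fake intensity, and every downstream statistic honors that mask.

**Working area.** The affine correction is exact at the control points and
degrades away from them. We formalize the "working area" as the closed
axis-aligned box through the axis points (`[-L, L]^2` mm, `L` the axis
length). `run_tilt_experiment()` replays the verification of this claim:
a graticule is imaged through a *true perspective* projection onto a
plate tilted 10°, the affine correction is solved from the three exactly
projected control points, and the residual at a test point 5 cm along
both axes (inside) is compared with the mirrored 15 cm placement
(outside). The inside residual is strictly smaller across source
distances 800-1200 mm and plate offsets 200-600 mm. Because the physical
source and plate distances of the original bench measurement are not
recorded, only this ordering — not the particular millimeter values — is
a meaningful target; with the package's default geometry (source 1000 mm,
plate 400 mm, a typical linac layout) the residuals are about 0.6 mm
inside versus 4 mm outside.

## Imaging: windowing and fusion

Display mapping is a standard window/level: a linear ramp of width
`window` centered on `level`, clipped to [0, 1].
`auto_window_level()` spans the 1st-99th percentile of the masked
intensities with the level at the midpoint; the percentile rule is
deliberately robust to the burned-in graticule, which otherwise drags a
min/max window. A constant image degenerates to a window of one intensity
unit.

`fuse_complementary()` assigns the windowed portal to one channel set and
the windowed DRR to the complementary set (red vs cyan by default). The
defining property — forced by requiring that perfectly aligned images
fuse to neutral gray — is complementary channel assignment with no alpha
blending; any blend satisfying gray-when-equal would be conformant, and
this is the simplest. Misalignment then appears as colored shadowing at
structure edges.

`shift_rotate()` is the manual nudge: a rigid content move of `(dx, dy)`
mm and a rotation about the isocenter. One caveat is documented rather
than hidden: for a combined shift and rotation, negating the parameters
inverts the operation only to first order (the exact inverse rotates the
shift vector); for the small rotations the adjustment models the
difference is negligible, and the test suite checks both forms.

## Registration: mutual information and the optimizer

Alignment quality is the mutual information of the joint intensity
histogram over the jointly valid overlap,

    I(A, B) = H(A) + H(B) - H(A, B),

with Shannon entropies in bits and all three terms computed from the same
joint histogram (so `I(A, A) = H(A)` holds exactly and `I >= 0` up to
rounding). Intensities are windowed to [0, 1] and binned into 64
equal-width bins by default: raw 10-bit axes would give a 1024 x 1024
joint histogram far too sparse at typical overlap sizes, while 64 bins
keep the estimate stable without washing out tissue contrast. The MI can
be restricted to the working-area box (default: on), which keeps poorly
corrected periphery from diluting the objective.

`auto_register()` searches the offset by multiresolution hill climbing.
At a fixed step the four axial neighbors are evaluated in a fixed order
(+x, -x, +y, -y) and the climb moves only on strict improvement —
equality is non-improvement, which prevents cycling and makes the path,
and therefore the result, fully deterministic. The step starts at 4 mm
(large enough to ride over local texture) and halves to a final 1 mm;
sub-millimeter final steps are supported. When rotation is enabled, a 1D
two-neighbor climb over rotation (default 2° halving to 0.25°, clamped to
±5°) alternates with the shift search until neither improves. The
defaults for the rotation schedule are package choices: the procedure is
specified as alternating to convergence, but no step sizes or ranges are
fixed by it, and setup rotations beyond a few degrees are clinically
implausible.

Determinism is a design requirement, not an accident: repeated runs on
identical inputs return bit-identical estimates, which is what makes the
method "perfectly consistent" in the repeat-presentation sense measured
by the evaluation module.

**Known failure mode.** MI needs exploitable intensity structure. When
portal contrast collapses — the situation for thick pelvic anatomy under
a megavoltage beam — the windowed anatomy histogram narrows into a few
bins, noise dominates the joint distribution, and the only reliably
shared structure left is the burned-in graticule, which sits at zero
offset by construction. The estimator then gravitates to zero shift
regardless of the true offset. The test suite reproduces this mechanism:
mean recovery error is non-decreasing as the synthetic contrast factor
falls through {1.0, 0.5, 0.2, 0.1, 0.05}, with a collapse below ~0.2 for
pelvis-like scenes.

## The synthetic phantom study

The generator exists so every claim above is testable without clinical
data; it emulates the design of a bench phantom study, not the physics of
megavoltage imaging.

- **Scenes** (`make_scene()`) are sums of analytic primitives. Chest
  scenes layer broad low-frequency anatomy (thoracic outline, graded lung
  fields, diaphragm domes, cardiac silhouette, mediastinum) under
  high-contrast, partly periodic ribs and vertebrae with seeded placement
  jitter; the broad structures are what give the MI objective its wide
  capture range, exactly as in real chest radiographs, while the periodic
  detail sharpens the optimum. Pelvis scenes are broad low-gradient blobs
  (iliac wings, sacrum, femoral heads), which is what makes their
  registration fragile once contrast is compressed.
- **The DRR** (`render_drr()`) is an orthographic render with a 10 x 10 cm
  field border, ticks every 1 cm, and an isocenter cross burned in at
  1023 on a 10-bit scale; anatomy is mapped to stay below the burn-in
  level so no clipping distorts its histogram.
- **Portals** (`render_portal()`) render the anatomy *shifted by the true
  offset* while the graticule stays at its nominal position — the
  graphics are anchored to the beam, the patient moved — which is what
  makes the known offset recoverable. Megavoltage degradation is modeled
  as linear histogram compression toward the mean by a contrast factor in
  (0, 1] plus seeded additive Gaussian noise; this is the simplest
  monotone-contrast knob consistent with attributing the pelvis failure
  to "lack of contrast", and it makes no claim to scatter or
  beam-hardening realism.
- **Case lists** (`make_case_list()`) draw five true offsets uniformly
  within ±10 mm per axis, present each twice (repeats share the noise
  seed, i.e. the same physical image shown twice), and shuffle the order.
  Chest cases default to contrast 0.5 with noise SD 15; pelvis cases to
  contrast 0.15 — megavoltage portals of thick anatomy retain far less
  subject contrast than thoracic ones, and these two settings place the
  chest suite in the regime where registration succeeds and the pelvis
  suite near its failure threshold.
- **Plate tilt** (`simulate_tilted_plate()`) is a full perspective
  projection (point source at 1000 mm, plate at 400 mm past the
  isocenter by default) that also returns the exactly projected control
  points, so the affine correction can be exercised against ground truth.

Default renders are 512 x 512 at 0.5 mm/px — a desk-scale stand-in for
1760 x 1760 CR plates that keeps a full ten-case study around five
seconds while leaving the graticule's share of image area close to the
full-scale situation. The optimizer unit tests use 192 x 192 at 1 mm/px
for the same reason; at much smaller sizes the graticule occupies
proportionally more of the image and can introduce a spurious zero-shift
local maximum that the full-scale configuration does not have.

What passing tests do **not** show: performance on real portal images,
whose scatter, veiling glare, double-exposure field edges and genuinely
projective anatomy are all absent from the generator. The phantom study
validates the optimizer's mechanics (capture range, exactness,
determinism, contrast sensitivity), not clinical accuracy.

## Evaluation statistics

`offset_distance()` is the Euclidean distance between estimated and true
offsets; `consistency()` the distance between the two repeat estimates of
one case. `summarize_records()` reports sample means and SDs (n-1
denominator — the convention choice is explicit since nothing in the
procedure fixes it). Distances classify into Good (<= 2 mm), Fair
(<= 5 mm), Poor (<= 10 mm) and Terrible (> 10 mm), boundaries resolved to
the smaller bin. `paired_t_test()` wraps the standard two-sided paired
t-test and refuses zero-variance differences instead of reporting p = 0.
`couch_correction()` maps a BEV shift to couch axes under a documented
convention (gantry about the longitudinal axis: `long = -dy`,
`lat = -dx cos g`, `vert = +dx sin g`); the feature is named by the
workflow but no formula is fixed by it, so the convention is anchored by
its two endpoints — at gantry 0 a BEV x shift is purely lateral, at 90°
purely vertical.

`run_phantom_study()` chains everything: scene, DRR, shuffled case list,
degraded portals, `auto_register()` at 4 to 1 mm steps with rotation off
(the study design uses pure translations), and record scoring. With the
chest defaults the mean distance between true and recovered offsets is
about 0.3-0.4 mm across seeds: true offsets are continuous while the
1 mm final step quantizes estimates to integer millimeters, so the floor
is the ~0.38 mm expected quantization distance, and the suite verifies
the mean stays within the 0.8 mm achieved by the method this package
reimplements.

## Numerical choices and degenerate inputs

- Bilinear interpolation everywhere an image is resampled; integer-pixel
  pure translations take an exact shift path (this is also what makes
  grid-search oracles bit-comparable with the hill climber).
- Samples pulling from outside an image or from masked pixels are
  background, excluded from histograms, MI, windows and summaries; an
  empty overlap is a contract error, not a zero.
- Histogram binning is equal-width over a stated range with terminal
  clamping; a degenerate range collapses to a single bin (entropy 0).
- Collinear or coincident control points, orientation-reversing linear
  maps, tilt >= 45° in the generator, rays parallel to the plate, and
  zero-variance t-test differences all raise informative errors.
- All randomness (scene jitter, offsets, noise, shuffling) flows from
  integer seeds through one derivation function; every artifact records
  the seeds that produced it.

## Limitations

- The tilt correction is the three-point affine model by design; no
  8-DOF homography or multi-point calibration is attempted, so accuracy
  degrades outside the working area (that degradation is measured, and
  bounded by staying inside the box).
- No automatic tick-mark detection: control points are supplied as pixel
  coordinates (interactively, via flags, or as JSON sidecars).
- The generator's contrast/noise model is deliberately minimal; absolute
  error magnitudes under heavy degradation depend on it and should not be
  read as clinical predictions.
- DICOM I/O is not provided (no reader in this package's dependency
  footprint); PNG, TIFF (including 10-bit-in-16-bit) and JPEG are.
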