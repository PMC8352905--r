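---
title: "Methods: volumetry of superior semicircular canal plugging"
author: "canalvol authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: volumetry of superior semicircular canal plugging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
`canalvol`. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement problem

After surgical plugging of a dehiscent superior semicircular canal (SC),
the plugged segment no longer carries the bright perilymph/endolymph signal
seen on heavily T2-weighted MRI. The quantity of interest is the *filling
defect*: the part of the preoperative labyrinth fluid space that is absent
postoperatively, expressed as a percentage of the preoperative labyrinth
fluid volume. Two properties of real scan pairs shape the whole design:

* the two visits have different intensity profiles (scanner gain/offset
  drift), so no single fixed threshold segments both scans correctly; and
* the two visits differ in voxel size and head pose, so the scans must be
  resampled and rigidly aligned before any voxelwise comparison; and even
  then the two segmented surfaces never match perfectly, so the raw
  difference contains thin surface-mismatch shells that must be removed
  before measuring.

## Grid and coordinate conventions

A volume is a 3D scalar array plus a 4×4 affine mapping *0-based voxel
indices, at voxel centers,* to world coordinates in mm (the NIfTI
convention). All registration math operates in world mm. Spacing is derived
from the affine's column norms; masks are stored as unsigned 8-bit NIfTI.
When the two scans' spacings differ, the lower-resolution scan is resampled
to the higher resolution — upsampling cannot destroy the ~1.2 mm canal
signal, downsampling demonstrably does (see the resampling tests:
thresholded fluid counts survive a 0.35→0.45→0.35 mm round trip within 2%
only for thick, volume-dominated structures). Intensities are interpolated
trilinearly; masks always nearest-neighbour, which preserves binarity and,
as the tests check, physical mask volume within 3% under rigid motion.

## Segmentation

Otsu's criterion is computed inside a user-declared region (an axis-aligned
box or an arbitrary mask) containing the vestibular structure: 256
equal-width bins spanning the region's observed min–max, candidate
thresholds at interior bin edges, between-class variance
$\sigma_b^2 = \omega_0\omega_1(\mu_0-\mu_1)^2$ maximized, ties broken
toward the lowest candidate. Foreground is *above*-threshold (fluid is
bright on T2); an `invert` flag covers dark-foreground uses. Because the
bins are recomputed from the observed range, the chosen bin index is
invariant under any positive affine intensity map — this is the property
that makes independent per-scan thresholds immune to inter-scan drift, and
it is asserted directly in the tests.

Two numerical notes. First, when the histogram has an empty valley between
two well-separated classes, $\sigma_b^2$ is constant across the valley and
the lowest-tie-break lands at the valley's *lower edge*, not its middle;
reference implementations (e.g. scikit-image) behave identically, and the
tests pin this behavior to a brute-force oracle rather than to a "midpoint"
intuition. Second, a constant region raises a "degenerate histogram" error
— the diagnostic for a region that missed the structure.

Cleanup keeps connected components (26-connectivity by default, so thin
canals do not fragment) with physical volume ≥ 1 mm³; specks of a few
voxels are noise at 0.35 mm resolution.

## Rigid registration

Six parameters: intrinsic Z-Y-X Euler angles (degrees) about the fixed
volume's field-of-view center, plus a translation in mm. The similarity
metric is normalized cross-correlation over the voxels whose pull-back
lands inside the moving field of view — invariant to the gain/offset drift
that same-modality pre/post pairs exhibit, so nothing stronger (mutual
information) is needed. The search is derivative-free: a three-level
coarse-to-fine pyramid (block-mean downsampling by 2), an exhaustive ±6 mm
translation grid at the coarsest level to set the capture range, Nelder–Mead
at every level, and a tight-simplex restart at full resolution for
subvoxel refinement. The full-resolution metric subsamples the fixed grid
by 2 per axis for speed; the returned metric is evaluated unsubsampled, and
the result is guaranteed not to fall below the metric at the initial
transform (otherwise the initializer is returned with a warning).

On default phantoms this recovers poses up to 10° / 5 mm within 0.1° and
0.05 mm — comfortably inside the one-voxel accuracy the defect measurement
needs (the acceptance suite enforces 0.5° / 0.35 mm).

The mirror mode reflects the volume across the mid-plane of its own field
of view along the subject left–right axis (identified from the affine's
direction cosines, or set explicitly). The reflection reverses the array
and keeps the affine, which makes double application the identity
bit-exactly; a rigid registration of the mirrored volume onto the original
then corrects head asymmetry, per the flip-then-align ordering.

## Defect extraction and quantification

The pipeline order is: resample → register post to pre → resample post onto
the pre grid (one trilinear pass) → segment both with independent
region-restricted Otsu thresholds → difference `pre AND NOT post` → clean →
relative volume. Segmenting the *aligned* post volume, rather than
transporting a natively segmented post mask with nearest-neighbour, was a
measured decision: mask transport produced coherent single-voxel crescent
artifacts along the whole labyrinth boundary, while thresholding the
resampled intensities keeps both iso-surfaces subvoxel-consistent (both
scans threshold at the same occupancy level thanks to Otsu's affine
invariance).

The manual edit step of the clinical workflow — removing difference voxels
outside the filling-defect region — is replaced by a deterministic, logged
emulation: intersect with a declared keep region, drop components below
1 mm³, and optionally keep only the largest component. The keep region
should follow the canal (a tube-shaped mask): an axis-aligned box around a
curved arc also admits the canal's continuation beyond the plug, which is
exactly where residual-misregistration shells accumulate. An optional
`trim_shell` step removes difference voxels 26-adjacent to the post mask;
it is off by default because at study noise levels it costs more true
defect (the plug's end caps) than it saves.

The primary output is relative: 100 × defect voxels / preoperative
labyrinth fluid voxels, with the ipsilateral labyrinth only as denominator.
Absolute mm³ is reported alongside. The contralateral mode uses the
mirrored healthy labyrinth as the reference denominator and flags the
"operated side has more fluid than its mirror" signature, which indicates a
swapped-side configuration.

## Direct volume rendering

Orthographic ray casting with a fixed step (default half the smallest voxel
spacing), piecewise-linear RGBA transfer function, and front-to-back
emission-absorption compositing
($C \mathrel{+}= (1-A)\,\alpha c$, $A \mathrel{+}= (1-A)\,\alpha$), with
early termination once every ray saturates ($A > 0.99$). The segmentation
mask gates opacity *and* the sampled intensities are zeroed outside the
mask, so rendered pixels are bit-independent of out-of-mask voxels (a
fuzz-tested invariant) at the cost of slightly darker in-mask boundary
samples. The default transfer function is an alpha ramp from the
mask-restricted Otsu threshold to the intensity maximum — a documented rule
standing in for an expert's histogram-guided choice. The defect overlay is
a two-material variant: defect voxels take an opaque blue, the remaining
labyrinth a translucent bone-white, defect-first where they overlap. Output
is PNG with straight alpha. Renders are style-matched to the clinical
workflow's views, never pixel-matched; cameras and transfer functions are
fully caller-controlled.

## Inter-rater agreement

The intraclass correlation for *average measures* is computed from the
two-way mean squares of a complete targets-by-raters table: with MSR the
between-target, MSC the between-rater and MSE the residual mean square,
the two-way random-effects absolute-agreement form is
$(\mathrm{MSR}-\mathrm{MSE})\,/\,(\mathrm{MSR} + (\mathrm{MSC}-\mathrm{MSE})/n)$
and the mixed consistency form is
$(\mathrm{MSR}-\mathrm{MSE})/\mathrm{MSR}$. Absolute agreement is the
default: raters measure the same physical volume, so systematic rater
offsets are real disagreement. Significance is the F test of MSR/MSE.
Qualitative bands overlap in common usage; the package uses <0.4 poor,
0.4–0.79 general, ≥0.80 good, the only ordering consistent with a 0.80
"good" edge. Any number of raters ≥2 is accepted.

## The synthetic phantom: what it emulates and what it does not

The phantom is the ground-truth engine for every end-to-end claim. One
labyrinth is three torus-shell canals in roughly orthogonal planes (the
superior and posterior canals in vertical planes at ±45° to the sagittal
plane, radii 3.2/3.0/2.8 mm, tube radii 0.6/0.55/0.5 mm), joined to a
vestibule ellipsoid (2.4 × 1.8 × 1.6 mm semi-axes), a cochlea blob and an
ampulla marker sphere (0.8 mm) at the superior canal's anterior junction;
landmark world coordinates (ampulla, common crus) are recorded in the
ground-truth sidecar. Geometry is labyrinth-like, not anatomically exact —
configurable, with these defaults frozen.

Voxelization happens on a 64³ grid at 0.35 mm isotropic spacing (96 voxels
on the left-right axis for bilateral phantoms), matching the study
acquisition. Partial volume is approximated by 3× supersampled occupancy
averaging in a band around the fluid boundary: thin tubes at this
resolution are boundary-dominated, and pure binary voxelization would make
segmentation unrealistically easy. The exact fluid mask is occupancy ≥ 0.5.
Binary voxelization (`partial_volume = FALSE`) exists for the bit-exactness
tests.

A simulated repeat scan applies, in order: intensity drift
(gain 1.1, offset 10 by default), a rigid pose change (3° plus ~1 mm by
default), and fresh additive Gaussian noise at 4.5 intensity units — 5% of
the 90-unit fluid–background contrast. These defaults are the study
conditions under which every end-to-end tolerance is stated; they are not
tuned per test. Noise is Gaussian, not Rician — sufficient to stress the
thresholding, noted as an extension. Seeding is local: the generator saves
and restores the caller's RNG state, and identical spec + seed give
bit-identical volumes.

A plug is an angular arc on one canal: every canal voxel whose centerline
angle falls inside the arc is set to background in the post scan, and the
removed mask voxels *are* the true defect — so the true relative defect is
a voxel count ratio, exact by construction. `plug_extent_for_fraction`
inverts this count to hit a target percentage; the inversion is exact up to
one voxel-step of arc. The angle origin convention (angle 0 along
$\hat u = \widehat{e \times n}$ with $e = \hat z$, or $\hat x$ for
near-axial canals) is fixed and re-derived independently in the tests.
Voxel-count fractions of a thin tube deviate from ideal angular fractions
by several percent depending on arc orientation — an orientation-dependent
voxelization effect the tests bound at 10% rather than pretend away.

What the phantom does **not** model: true membranous-labyrinth anatomy
(cochlear spiral, ampullae as dilations rather than marker spheres),
Rician noise statistics, susceptibility or motion artifacts, bias fields,
and partial plugs that narrow rather than interrupt the canal. Passing the
phantom suite therefore demonstrates the pipeline's numerical correctness
and its robustness to drift, pose and noise at clinical magnitudes — not
clinical segmentation accuracy on patient data.

## Numerical choices and degenerate inputs

* Histogram: 256 bins over observed min–max; at least two distinct values
  required, else "degenerate histogram".
* Resampling fill value: the histogram mode of the source volume (the dark
  background in this modality).
* Component connectivity 26 and 1 mm³ floor throughout, so the decision
  rule "relative defect > 1% means plugged" is not driven by speckle.
* Tie-breaks: lowest Otsu candidate; first-encountered component label;
  defect-first color priority in overlays.
* Rotation parameterization is frozen (intrinsic Z-Y-X about the fixed
  FOV center); transforms serialize to JSON with the convention named.
* Empty results (defect, segmentation) warn and return empty rather than
  erroring: a zero defect is a clinically meaningful "failure group"
  signature, not an exception.

## Problem sizes used in validation

The shipped validation runs on 64³ phantoms (96×64×64 bilateral): five
registration recoveries at perturbations up to 10° / 5 mm, a four-point
plug-fraction sweep spanning 0–9% of labyrinth volume, a twenty-phantom
plugged/unplugged cohort classified at the 1% threshold, drift-null and
mirror-symmetry controls, and the compositing closed form
$A = 1-(1-\alpha)^n$. These sizes keep the full suite in a few minutes on
one CPU while leaving every tolerance comfortably met; all of them are
recomputed, not stored, by `scripts/acceptance.R`.

## Known limitations

Registration is global-rigid only; a labyrinth-local refinement ROI is
possible but not default. The keep region must be declared by the analyst
(the package's phantom helpers derive it from ground truth; on patient data
it encodes the analyst's judgment, as the manual edit did). ICC handles
complete tables only. DICOM ingestion, CT co-registration and deformable
registration are out of scope.
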