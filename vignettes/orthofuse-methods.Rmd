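---
title: "Multi-sensor orthodontic model construction: methods and design notes"
author: "orthofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor orthodontic model construction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orthofuse` builds per-tooth manipulable 3D orthodontic models by fusing
two complementary sensing routes: structured-light surface scanning (crowns
and gingiva, sub-0.1 mm accuracy, nothing below the gum line) and cone-beam
CT (roots and alveolar bone, ~0.4 mm voxels, poor crown fidelity). This
vignette records the models, the parameters that matter, and the design
decisions taken where the methodology is genuinely open.

## The synthetic phantom: what it emulates, and what it does not

All stages are validated on parametric jaw phantoms. A tooth is a
superellipsoid-profile crown (exponent 4 cross sections, semi-axes
`crownRadii`, dome-shaped occlusal tip, a neck that narrows linearly to 55%
of the crown width over the lower 30% of the crown) joined to one to three
tapered-capsule roots whose radius shrinks by `rootTaper` toward a smoothly
rounded apex. Every cross section perpendicular to the tooth axis is
closed-form — superellipses for the crown, circles (with lens-overlap
corrections while multi-root trunks are merged) for the roots — so the
generator can answer, analytically, exactly the questions segmentation
accuracy is measured by: cross-section areas, boundary distances, tooth
volumes, and the furcation depth where a multi-root contour must split.
The apex is rounded (rather than a blunt truncated cone) so the
cross-section area reaches zero continuously; a blunt end would leave a
sub-threshold residual contour with no analytic counterpart.

Teeth are placed on a circular arch with a configurable interproximal gap
(default 0.8 mm) and wrapped in a gingiva sheet: a gentle ridge away from
the teeth plus a steep collar rising to just below the margin height at
each crown wall, which makes the margin line the sharpest crease on the
mouth model — the property the curvature-based segmentation exploits.
Bone is an arch-following slab containing every root; soft tissue wraps
both. Voxelization assigns tissue Hounsfield-like values
(tooth 1500 > bone 900 > soft 300 > background 0) at voxel centers with
i.i.d. Gaussian noise (default SD 30 HU) and optional metal-streak
artifacts (attenuated rays through a "metal" point at a crown). Real CBCT
noise is spatially correlated and beam-hardening artifacts are structured;
the phantom makes no claim to scanner realism — passing tests demonstrate
correctness of the algorithms under controlled conditions, not clinical
performance.

Complementary surface scans emulate the two optical acquisition routes:
impression-mode scans miss a 1.2 mm band at the cusp tips (impression
material cannot reach them), cast-mode scans miss the interproximal walls
(optical undercuts between adjacent teeth). Each simulated view is a
visibility-culled, area-weighted surface sample; occlusion is not ray
traced. All randomness is seeded per operation, and identical seeds give
bit-identical outputs.

## Structured-light stage

The binary stripe projector halves its stripe period at each of `n`
temporal patterns, so a pixel's bright/dark history read MSB-first is its
stripe code and the coding provides `2^n − 1` encoded line boundaries.
Decoding binarizes each pixel against the midpoint of its own min/max
across the stack (robust to albedo, no extra captures); pixels with
contrast below a floor are masked. Triangulation intersects the camera
pixel ray with the decoded stripe's light plane. The simulated rig uses an
orthographic camera and a projector tilted 30° about the vertical axis;
pixel columns are aligned with stripe centers on the reference plane so
the flat-reflector round trip is exact to numerical precision, which is
the property the round-trip tests pin down. The phase-shift refinement
sometimes combined with temporal binary coding is not modeled — only the
binary stage is specified by the methodology this package implements.

## Surface variation and crown segmentation

For each sample point the covariance of its 2 mm spherical neighborhood is
eigen-decomposed (`λ0 ≤ λ1 ≤ λ2`); the surface variation
`δn = λ0/(λ0+λ1+λ2)` is 0 for a coplanar neighborhood and 1/3 for an
isotropic one, and the eigenvector of `λ0` estimates the normal. The 2 mm
radius matches the scale of margin-line creases on human teeth; smaller
radii amplify sampling noise, larger ones blur adjacent features together.
Normals are oriented away from a reference interior point (the centroid by
default) — the mouth surfaces used here are star-shaped enough for that;
a minimum-spanning-tree propagation would be needed for general scenes.

Margin lines are closed periodic cubic splines through ordered seed points
under chord-length parameterization (seeds are supplied as files/matrices,
replacing interactive clicking). Crown/gingiva separation grows a region
from a seed inside each margin loop across mesh edges, with the projected
loop acting as a barrier, then relaxes the boundary onto the
surface-variation ridge: blocked vertices within a 1 mm band join the
crown when their `δn` reaches the median ridge level. Splines are fit in
3D and projected, rather than in a 2D parameterization — the arch
geometry makes either workable, and 3D avoids choosing a parameterization.

## CBCT stage

**Threshold optimization.** Iso-gray surfaces are extracted by marching
tetrahedra (six tetrahedra per grid cube; triangles oriented down-gradient)
after optional 3D Gaussian pre-smoothing (σ = 0.8 voxel in the sweep) that
suppresses noise speckle without displacing symmetric boundaries. For each
candidate threshold the optical crown is landmark-aligned (Kabsch), refined
by ICP restricted to mating pairs within δ_ε = 1 mm, and scored by the mean
absolute point-to-surface discrepancy over mating pairs (the sign of the
discrepancy is not used). τ_opt minimizes the mean discrepancy, ties toward
the lower threshold. On phantoms the optimum falls at the half-intensity
boundary between tooth and surrounding tissue, as expected for symmetric
blur + noise. The sweep crops the volume to the crown's bounding box plus
4 mm: mating is restricted to 1 mm anyway, and the crop keeps the
iso-surfaces small.

**DRLSE.** The energy combines a double-well distance-regularization term
(weight μ), an edge-weighted contour-length term (λ), and a signed balloon
term (α; positive shrinks a contour initialized outside the target). The
evolution equation, double-well potential `p`, and smoothed Dirac/Heaviside
(width ε = 1.5 px) follow the standard distance-regularized formulation;
the regularizer is discretized as `div((p'(s)/s − 1)∇φ) + ∆φ` with a
five-point Laplacian — the naive nested central-difference form decouples
the grid parity and destroys the solution. Explicit Euler stepping requires
`Δt·μ < 0.25`, enforced before evolving. Slices are rescaled to [0, 90]
before the edge indicator: the scale controls how saturated `g`'s valley is
at strong edges — on the raw HU scale `g ≈ 0` in a flat multi-pixel band
around every edge and the contour stalls on the valley shoulder, while at
gradients of order one the `∇g` attraction stays informative across the
valley.

**Crown-guided initialization and propagation.** The starting slice is the
slice whose closed intersection with the aligned optical crown has
*maximal* area (subject to a 4-voxel-area floor); the intersection region
R0 is dilated by a 3 px disk and the LSF initialized as a binary step
(−2 inside, +2 outside). Propagation then sweeps from the starting slice
toward the root apex and, in a second pass, toward the crown tip; each new
slice is initialized from the previous slice's converged region re-dilated
by 1 px. Starting at the maximal section means every propagated step faces
a *tapering* cross section, which is the regime a positive-α
(shrink-biased) evolution handles; starting at the first (dome-apex)
intersection — the literal reading of the initialization recipe — forces
the contour to grow against the balloon and was measured on phantoms to
undersegment tooth volume by ~27%, versus ~2% for the max-section start.
That measurement drove the design change. Propagation stops when the
segmented area falls below 2 voxel areas, and an area growth beyond 3×
between adjacent slices raises a divergence error. Impacted teeth, absent
from the optical scan, take the manual path: a polygon contour and start
slice supplied as data.

**Stage defaults** (all configurable, recorded with every pipeline run):
μ = 0.2, λ = 2, α = 0.5, σ = 1.5 px, Δt = 1, 150 iterations per slice.
They were calibrated on phantoms by sweeping volume and contour accuracy —
the methodology itself prescribes experimental parameter setting — and
then frozen. λ trades edge attraction against curvature shrinkage of thin
roots: λ = 14 gives slightly better single-root contours but crushes
≲1 mm twin roots before their furcation; λ = 2 keeps both (10-seed volume
error ≤ 2%, mean contour distance 0.26 mm at 0.4 mm voxels, correct 1→2
loop split below the furcation).

**Bone.** The bone envelope takes the manual initialization path (there is
no optical guidance for bone), and the socketed bone region is the filled
bone mask minus every filled tooth mask, per slice; tooth contours outside
the bone raise a warning and the subtraction proceeds.

## Fusion and the multi-body model

The optical crown is authoritative for crown geometry: its vertices and
faces enter the fused tooth verbatim. CBCT faces on the crown side of the
crown's rim plane are discarded, and the cut root boundary loop is
stitched to the crown rim by an angular merge around the rim normal
(default seam band 0.5 mm); faces carry `optical`/`cbct`/`seam` provenance
tags. Bodies in the multi-body model share no vertices; each tooth carries
its own rigid pose, and collision reporting uses a sampled point-in-mesh
parity test (not exact mesh booleans) — adequate for flagging
interpenetration during treatment simulation, not for contact mechanics.

## Numerical choices and limitations

- Volumes follow the center-of-voxel convention
  `world = origin + index·spacing`; all coordinates are mm.
- Contour-to-truth distances are measured radially against the analytic
  cross-section (exact for circles, a tight bound for the near-circular
  superellipses).
- DICOM support is a minimal explicit-VR little-endian CT reader/writer
  (geometry and rescale tags honored, intensities quantized to integer
  HU); it is not a general DICOM implementation.
- Model export writes ASCII STL: binary STL stores float32, which cannot
  round-trip 30 mm coordinates to the micrometer fidelity the export
  contract promises.
- Zero-level contours are extracted from a border-padded field, so a
  region clipped by the image boundary still yields a closed loop traced
  along the border.
- ICP is point-to-point with distance rejection; it refines a coarse
  (landmark or centroid) alignment and is not a global registration —
  initializations beyond ~20° may fall into local minima. Mutual-nearest
  filtering is available but off by default because it narrows the
  convergence basin.
- Level sets are strictly 2D slice-by-slice, as the methodology specifies;
  no 3D level set, no GPU path, full-domain updates within a cropped ROI.
- Problem sizes in the test suite (128³ voxels at 0.4 mm for the recovery
  studies, ~10⁴-point clouds for registration) were chosen as the smallest
  sizes at which the geometry is resolved by several voxels everywhere;
  the algorithms have no intrinsic size limits.
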