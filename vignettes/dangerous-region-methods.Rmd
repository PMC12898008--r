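---
title: "Dangerous-region generation for bone tumor resection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dangerous-region generation for bone tumor resection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomargin)
```

## The problem

In computer-assisted resection of pelvic bone tumors, the surgeon plans a
set of osteotomy (bone-cut) planes that must stay at least a prescribed
safety margin — typically 10, 15 or 20 mm — away from the tumor everywhere
in 3D. Conventional navigation shows the tumor and the planes but gives no
direct feedback on whether every point of every plane actually honors the
margin. The *dangerous region* makes that check trivial: it is the tumor
plus all surrounding tissue within the margin, a single solid whose
boundary is the margin isosurface. A planned cut is admissible exactly when
its plane does not intersect the region.

`osteomargin` builds this region from segmented tumor (and optionally bone)
masks on the CT voxel grid, reconstructs a closed triangulated surface for
it, and checks plane clearances. A separate module reproduces the clinical
summary statistics of the 19-patient pelvic-tumor cohort that motivated the
method.

## The pipeline

Given a binary tumor mask with per-axis spacing $(s_x, s_y, s_z)$ in mm and
a margin $m$:

1. **ROI crop.** The tight foreground bounding box is padded by
   `pad_mm` (default $m + 20$ mm, converted per axis with `ceiling`) and
   clipped to the grid. Everything downstream happens on this crop. If the
   tumor still touches the crop boundary the run aborts
   (`pad-too-small`) rather than silently truncating the region.
2. **Anisotropic distance transform (ADT), sparse.** The exact Euclidean
   distance from every voxel center to the nearest tumor voxel center, in
   world mm, computed by separable lower-envelope (parabola) sweeps over
   squared distances with $s_a^2$ weights — one pass per axis, $O(N)$, and
   exact to floating point rather than a chamfer approximation. Exactness
   is what makes the brute-force all-pairs oracle in the test suite a
   meaningful check (`< 1e-9` mm agreement).
3. **Dense grid.** The crop is refined to `dense_spacing` (default: half
   the smallest source spacing, isotropic — a resampling ratio of 2; the
   ratio is configurable because the appropriate refinement depends on the
   source resolution). The ADT is recomputed there, giving the dense map.
4. **Coarse region and refinement shell.** On the sparse map, voxels with
   $d \le m - b$ form the trusted interior, where the band
   $b = \tfrac12\sqrt{s_x^2+s_y^2+s_z^2}$ (half the source voxel diagonal)
   is the maximal decision uncertainty a sparse voxel can carry. Voxels
   whose nearest sparse neighbor has $d \in (m-b,\, \cdot\,]$ are the
   uncertainty shell: only there is membership re-decided at dense
   resolution, as $d_\text{dense} \le m$. The margin test is inclusive —
   a point exactly at the margin is dangerous — which is the conservative
   choice for a safety construct.
5. **Combination.** The final dense mask is the union of the
   nearest-neighbor-upsampled interior and the re-decided shell. Boundary
   points are the centers of dense foreground voxels with at least one
   background 6-neighbor. Optionally the mask is clipped to bone ∪ tumor
   (`restrict_to_bone`; off by default, since the region is meant to
   include *all* tissue within the margin, not only bone).
6. **Surface.** The boundary point cloud is Delaunay-tetrahedralized and
   sculpted into a closed, watertight triangle mesh (below), exportable as
   binary STL or ascii PLY for planning systems.

Every stage is deterministic; identical inputs and configuration give
bitwise-identical masks and reports.

### Why a two-resolution scheme

Thresholding the dense map alone would give the same accuracy but costs a
full high-resolution transform over the whole ROI; thresholding the sparse
map alone leaves a staircase boundary whose error is half a source voxel
diagonal (3 mm CT slices make this ~1.6 mm — clinically relevant when the
margin itself is 10 mm). Trusting the sparse map away from the isosurface
and refining only the shell bounds the boundary error by half a *dense*
voxel diagonal while keeping most of the volume at coarse resolution.

### What the dense map measures (a deliberate choice)

All distances, sparse and dense, are measured to the **tumor voxel
centers** (the solid set; the map is zero inside the tumor). On the dense
grid the centers are represented by snapping each source center to its
nearest dense voxel, exact for integer refinement ratios. The alternative —
measuring to the trilinearly resampled tumor's 0.5-level set — represents
the tumor surface with sub-voxel smoothness, but biases the dense map
relative to the center-based definition by up to half a *source* voxel
(about 1.2 mm in re-entrant corners, measured on blob phantoms). Since the
region is *defined* as the dilation of the segmented tumor voxels, and
since a single consistent reference is needed for the coarse and dense maps
to agree, the center convention is used throughout. Its cost: the region
boundary inherits the source grid's sampling of the tumor surface, so
against an analytic phantom the boundary can sit up to roughly half a
source voxel diagonal inside the true dilated surface. The two conventions
differ by at most half a source voxel diagonal, below the CT slice
thickness that dominates real segmentation uncertainty.

Similarly, a naive union of "interior" and a ring thresholded as
$d_\text{dense} \in (m-b, m]$ leaves pinholes: a dense voxel can have
$d_\text{dense} \le m-b$ while its nearest coarse voxel sits just outside
the trusted interior, so neither test admits it. Re-deciding the *coarse
map's* uncertainty shell (rather than a dense-distance annulus) closes
these holes; `fine_ring()` still exposes the plain annulus operation.

## Binary resampling

`resample_mask()` interpolates the 0/1 indicator trilinearly at the output
voxel centers and thresholds at 0.5, ties mapping to foreground. The output
grid shares the input origin (voxel-center convention; the header frame is
never flipped) and is the smallest grid covering the input's physical
extent. Note a property of the trilinear dialect worth knowing: at edges
and corners of a solid the interpolant is the product of per-axis weights,
so a point on a cube's corner has value 0.25 and is *not* foreground; the
0.5-level set is slightly rounded at convex corners.

## Surface reconstruction

`reconstruct_surface()` turns the boundary cloud into a watertight mesh:

* **Delaunay tetrahedralization** (incremental Bowyer–Watson with an
  enclosing super-simplex, orientation-walk point location, and
  star-shaped cavity repair). Voxel-center clouds and points sampled on a
  sphere are exactly cospherical — the worst case for the in-sphere
  predicate — so predicates are evaluated on a deterministic, index-keyed
  perturbation of about $10^{-8}$ of the cloud diameter; reported vertex
  coordinates are always the originals. Exactly coplanar inputs are
  rejected (`degenerate-geometry`), never nudged into validity.
* **Sculpting.** `shrink = 0` returns the convex hull (the boundary of the
  full complex). For `shrink > 0`, boundary tetrahedra are peeled, longest
  exposed edge first, while the complex remains a topological ball:
  removals are allowed only with one boundary face (opposite vertex
  interior) or two (opposite edge interior), so the boundary stays a
  single watertight 2-manifold and every input point remains a vertex or
  strictly inside. The peel threshold interpolates geometrically from the
  longest complex edge (no peeling) down to twice the median
  nearest-neighbour spacing at `shrink = 1`. Peeling is also required to
  *descend* — a removal may not expose faces with longer edges than the
  ones it removes — which stops the carve from tunnelling along interior
  chords of well-sampled convex regions. Circumradius ordering, the
  classical alpha-shape criterion, was rejected: on surface-sampled clouds
  every circumsphere degenerates to the sampled surface itself and the
  ordering becomes noise.

The supporting tetrahedral complex is kept on the object, so enclosed
volume and point-containment queries are exact with respect to the mesh.

## Plane clearance

An osteotomy plane is a point plus a unit normal, the normal pointing away
from the tumor into the half-space that must remain free of dangerous
tissue. Clearance is the minimum over all region voxel centers of
$(\mathbf{p}_0 - \mathbf{p})\cdot\hat{\mathbf{n}}$: positive means the
whole region stays behind the plane by that many mm, negative gives the
penetration depth, and "safe" is clearance $\ge 0$. Using all foreground
centers (not only boundary points) keeps the answer right even for planes
that intersect the region without crossing its sampled boundary points.

## Phantoms

`make_phantom()` voxelizes spheres, axis-aligned ellipsoids, two-lobe
unions, and seeded random blobs (3–7 overlapping ellipsoids), with an
optional spherical-shell bone sector, by a voxel-center inclusion test —
no partial-volume fractions, so voxel-count oracles are exact. Ground
truth carries closed-form volumes; for the sphere the margin-dilated
volume $\tfrac43\pi(r+m)^3$, and for the ellipsoid the Steiner formula
$V + Am + Mm^2 + \tfrac43\pi m^3$ with the area $A$ and mean-curvature
integral $M$ evaluated by high-order Gauss–Legendre quadrature (they
reduce to $4\pi r^2$ and $4\pi r$ for equal semi-axes, which the tests
check).

What the phantoms emulate: compact solid tumors at CT-like isotropic and
anisotropic spacings, including non-convex and disconnected shapes. What
they do not: real pelvic anatomy, segmentation noise, intensity
information, or inter-annotator variability — so passing phantom tests
demonstrates geometric correctness of the pipeline, not robustness to
imperfect segmentations.

## Cohort statistics

The packaged fixtures mirror the study's two tables column-for-column
(19 patients: Enneking resection type, follow-up months; osteotomy margin,
operative time, blood loss, MSTS score, recurrence/metastasis, vital
status). The loader enforces the structural invariants (19 rows, deaths at
ids 2 and 6, one missing MSTS at id 14, MSTS within 0–30).

```{r cohort}
cs <- cohort_summary()
unlist(cs[c("operative_time_mean", "operative_time_median",
            "blood_loss_mean", "blood_loss_median",
            "msts_mean", "recovery_mean_pct",
            "km_60_pct", "km_60_wide_pct")])
```

Conventions worth stating:

* **Event times.** Each death enters the Kaplan–Meier estimator at that
  patient's tabulated follow-up duration (17 and 50 months); everyone else
  is censored at follow-up. The narrative death times in the text (33 and
  50 months) conflict with the table for one patient; the tabulated
  durations are used because they are the patient-level data.
* **MSTS cohort.** The 16 eligible scores are the 19 patients minus the
  two deaths and the one missing entry.
* **Wide-resection subgroup.** The two marginal-resection patients are
  identified computationally as the unique (Type I + II, Type II + III)
  pair whose mean operative time equals the reported marginal-group mean
  (367.5 min) — an exhaustive search over the eight candidate pairs, not a
  hard-coded id list.
* **Rounding.** Half-up at the printed precision (integers for minutes and
  mL, one decimal for MSTS means, percentages and survival × 100), via
  `round_half_up()`; base `round()` rounds half to even and would disagree
  at exact halves.
* The Kaplan–Meier product-limit computation itself is delegated to the
  `survival` package; the test suite cross-checks it against an
  independent hand-rolled estimator on random censored samples.

## Numerical choices and degenerate inputs

* Distances: exact separable transform; `1e30` sentinel for empty
  scanlines; results are 1-Lipschitz per axis by construction.
* Thresholds: margin and ring bounds inclusive on the dangerous side.
* Resampling ties (interpolant exactly 0.5) are foreground; a `1e-12`
  guard absorbs floating-point noise at ties.
* Empty masks, negative pads, bands wider than the margin, non-positive
  spacings, coplanar point sets, mismatched grids and missing files all
  raise distinct classed errors (`osteomargin_empty_foreground`,
  `osteomargin_pad_too_small`, `osteomargin_grid_mismatch`,
  `osteomargin_missing_file`, or plain argument errors); the command-line
  wrapper maps these classes to distinct exit codes.
* The pipeline contains no randomness; phantoms take an explicit seed
  (mandatory for blobs) and restore the session RNG state.

## Problem sizes used in the checks

The validation suite exercises: random anisotropic masks up to $20^3$
against all-pairs brute force; blob/two-lobe/sphere phantoms on grids up
to about $100^3$ source voxels with dense grids up to about $200^3$ for
the analytic-dilation benchmark (sphere $r = 8$ mm, margin 20 mm, 1 mm
source / 0.5 mm dense); and surface clouds up to a few tens of thousands
of points. These sizes were chosen so the full suite completes in a few
minutes on a single core while every stage is still exercised at clinical
anisotropies; clinical ROIs are of the same order once cropped.

## Known limitations

* Axis-aligned world frames only; rotated NIfTI transforms are not
  resliced (the mask is used in its own header frame).
* The region boundary inherits the source grid's discretization of the
  tumor surface (see the dense-map discussion above); against analytic
  phantoms this shows up as a systematic deficit of up to about half a
  source voxel diagonal, independent of the dense spacing.
* Single-component tumors are assumed for surface reconstruction at
  `shrink = 1` (the sculpted complex never disconnects); disconnected
  tumors yield one enclosing surface spanning the components.
* The sculpting threshold at `shrink = 1` is a heuristic tuned to
  uniformly sampled voxel-boundary clouds; extremely uneven sampling can
  leave bridging faces that a smaller threshold would remove.
* No DICOM reading, no registration, no segmentation: masks are inputs.
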