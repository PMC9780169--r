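---
title: "From CT volume to printable wound patch: methods and design notes"
author: "woundpatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT volume to printable wound patch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large soft-tissue defects — volumetric muscle loss (VML) from trauma or
tumour resection — exceed the body's capacity to regenerate and heal by
scarring. One therapeutic route is to fill the wound with a bioprinted
scaffold of decellularized extracellular matrix (dECM) hydrogel shaped to
the individual wound, so that the scaffold contacts the wound bed everywhere
and delivers matrix at a uniform dose. That requires a digital chain from a
CT scan of the open wound to (i) a patient-specific, uniform-thickness patch
model, (ii) printable toolpaths, and (iii) quantitative evidence that the
printed and implanted scaffold is dimensionally accurate and conformal.

`woundpatch` implements that chain as testable, deterministic R code, and
pairs it with a synthetic CT phantom generator so that every stage can be
validated against analytic ground truth at desk scale — the original canine
and human scans behind this class of workflow are not publicly available.

## Pipeline overview

1. **Segmentation** (`threshold_volume`, `largest_component`,
   `invert_wound`). The wound is an air-filled crater: automatic (Otsu) or
   fixed thresholding extracts the air side, the largest connected component
   of the complement is the tissue, and complementing the tissue inside a
   user-supplied region of interest yields the cavity — the solid that is
   directly conformal to the wound-bed surface. The ROI stands in for the
   interactive cropping a clinician would do; its top face belongs at the
   skin plane.
2. **Patch design** (`make_shell`, `trim_footprint`, `smooth_mask`,
   `mask_to_mesh`). The patch is the set of cavity voxels within a fixed
   distance of the wound-facing interface — a uniform-thickness shell grown
   by Euclidean distance transform (EDT), the voxel-native equivalent of
   hollowing a solid from its external surface. Default thickness 4 mm:
   thick enough for handleability, thin enough to drape. The shell is
   trimmed to the wound's projected footprint, median-filtered (3-voxel
   window), and meshed.
3. **Toolpaths** (`make_toolpath`, `plan_gcode`, `write_gcode`). A minimal
   slicer: mid-layer planar cross-sections, perimeter insets, rectilinear
   infill with spacing `width / density`, optional regional density/angle
   modifiers, and volumetric G-code (E = cumulative mm³) with bioink-volume
   and print-time estimates. Defaults are the study conditions: 0.16 mm
   layers, 20 mm/s, 2 perimeters, 2 top/bottom layers, 40 % infill with
   connected lines and 50 % infill overlap, 0.4 mm extrusion width — at
   which the spacing law reproduces the observed ~400 µm filaments spaced
   ~1000 µm apart. A fixed 45° infill angle emulates unipennate muscle-fibre
   architecture; thirds at 20/30/40 % reproduce graded-density scaffolds.
4. **Gauging** (`sample_surface`, `align_bbox_centers`, `icp_refine`,
   `cloud_to_cloud`, `gauge_meshes`). Dimensional accuracy between two
   surface models: area-weighted surface sampling, coarse alignment by
   bounding-box centres, fine alignment by trimmed point-to-point ICP
   (Kabsch/SVD update, worst 10 % of matches dropped), then per-point
   nearest-neighbour distances summarised as a mean unsigned deviation and a
   0.1 mm-bin histogram — the conventions of standard cloud-comparison
   practice.
5. **Conformality** (`detect_voids`, `split_top_bottom`,
   `contact_percentage`, `compare_void_volumes`). Interface air pockets are
   26-connected components of air voxels that touch both the patch and the
   wound and are not open to the scan boundary; components below 0.001 mm³
   are disregarded. Contact is the literal surface-area ratio
   `area(bottom of scaffold) / area(top of wound) x 100` after cropping both
   models to a common footprint. Void-volume sets are compared on log10
   volumes with Shapiro–Wilk and F-test assumption checks reported (never
   used as gates) and a two-tailed unpaired Student t-test.
6. **Contralateral workflow** (`mirror_mask`, `boolean_subtract`,
   `scale_mesh_to_volume_fraction`, `contralateral_scaffold`). For a
   unilateral injury with healthy contralateral anatomy: mirror the healthy
   compartment across the mid-sagittal plane, subtract the injured side,
   mesh the difference, and scale it to a volume fraction (default 70 %,
   the syringe-capacity compromise) isotropically about the volume centroid.

`run_pipeline()` orchestrates phantom → segment → design → slice → place →
gauge → conform with a validated config, per-stage artifacts, MD5 manifest
and stage-level resume.

## What the phantom generator emulates — and what it does not

`make_limb_wound_phantom()` builds a limb as a tissue cylinder (≈40 HU) in
air (−1000 HU) whose top is cut by a flat "surgical field" plane, with a
crater carved into that plane: a hemisphere (radius = depth), a
superellipsoid (exponent 4 — the boxy template-like wound; defaults 100 × 70
mm footprint, 25 mm deep, the study's wound scale), or a lobed ellipsoid.
Defaults image at 0.35 mm isotropic voxels, the CT protocol resolution. The
flat top is deliberate: it makes the cavity equal the analytic crater shape
exactly, so segmentation accuracy, inversion volume and shell thickness can
be scored against closed forms. An analytic crater-surface mesh (vertices
exactly on the implicit surface) accompanies every phantom.

`make_placed_patch_phantom()` voxelizes a patch mesh back onto the wound
grid at an elevated grey value (300, mimicking barium-sulfate contrast),
optionally after a rigid placement perturbation, and carves spherical air
voids of exactly known voxel volume at the interface.
`make_bilateral_phantom()` builds mirrored limb pairs with an ellipsoidal
muscle compartment, the injured side missing a prescribed volume fraction.

Not emulated: realistic CT noise spectra and beam hardening, anatomical
atlases, soft-tissue deformation during implantation, skin contracture.
Passing tests therefore demonstrate the correctness of the *digital*
operations under clean, separable contrast — not robustness to clinical
image quality, which in the real workflow was handled by manual cleanup.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| voxel spacing | 0.35 | mm | CT protocol resolution |
| shell thickness | 4 | mm | structural integrity vs drapability |
| median window | 3 | voxels (diameter) | removes voxel detail without shape loss |
| layer height | 0.16 | mm | embedded-printing layer resolution |
| extrusion width | 0.4 | mm | 23-gauge needle, ~400 µm filament |
| infill density | 0.40 | fraction | handleable stiffness within syringe volume |
| infill overlap | 0.5 | fraction of width | fuses infill to perimeters |
| print speed | 20 | mm/s | F1200 in the emitted G-code |
| min void | 0.001 | mm³ | reporting floor for interface pockets |
| volume fraction | 0.7 | — | fits the 25 mL syringe capacity |
| ICP trim | 0.1 | fraction | robustness to partial overlap |
| surface samples | 1e5 | points | deviation statistics resolution |

## Numerical choices

- **Grid convention.** Axis-aligned voxel grids, voxel-centre world mapping
  `world = origin + index * spacing`; no orientation matrices. NIfTI I/O via
  RNifti (spacing/origin in the sform); NRRD and binary STL read/written
  directly (raw little-endian).
- **Isosurfaces** use marching tetrahedra (each cube split into the six
  tetrahedra around its main diagonal, vertices deduplicated on tetrahedral
  edges). Unlike table-based marching cubes this is watertight by
  construction on binary fields — there are no ambiguous cases — at the cost
  of more triangles. On binary data all surface vertices are edge midpoints;
  volumes of smooth shapes are accurate to well under 2 %, while *areas* of
  staircase surfaces are systematically inflated, which is why conformality
  is a ratio of two areas measured on the same grid.
- **Shell rule.** `distance < thickness`, strictly: with `<=` a flat slab at
  commensurate spacing would carry one extra voxel layer and the volume
  identity `A x t` would fail. Wall thickness is estimated as twice the
  interior EDT on medial (ridge) voxels minus one spacing, correcting the
  centre-to-boundary half-voxel offset.
- **Smoothing never detaches the patch.** The median-filtered shell is
  re-intersected with the cavity and the wound-facing interface layer is
  re-added; otherwise the filter can shave single interface voxels and
  manufacture spurious 0.04 mm³ "voids" between a patch and the wound it was
  designed for.
- **Perimeter insets** are contours of a signed Euclidean distance raster of
  the slice polygon (pixel = width/4, marching squares at `(i + 1/2) x
  width`), accurate to about half a raster pixel; infill lines are clipped
  *exactly* against polygon loops (even-odd rule) so perimeter-free fill
  fractions are exact. The infill line family sits at offsets
  `(m + 1/2) x spacing` from the world origin: deterministic, and never
  degenerate on the boundary of grid-aligned parts.
- **Slicing planes** are mid-layer (`z_min + (k + 1/2) h`) and are nudged by
  `1e-3 h` if they would pass through a mesh vertex.
- **Void candidacy** requires touching both the patch and the wound within
  one voxel and *not* reaching the scan boundary (ambient air is never a
  void). In `split_top_bottom`, faces whose normal has zero component along
  the up axis (vertical walls) belong to neither submesh; the top and bottom
  areas therefore sum to the area of faces with nonzero normal component,
  and a slab's bottom area equals its footprint exactly.
- **Mesh-mode distances** in `cloud_to_cloud` use a dense area-weighted
  resampling of the reference mesh with a grid-accelerated nearest-neighbour
  search, not exact point-to-triangle distance; `gauge_meshes` measures its
  final deviations that way so the report reflects misalignment rather than
  the sampling density of the comparison cloud.
- **Mirroring** snaps the mirror plane to the nearest half-voxel so
  reflection is an exact index permutation: volume is preserved exactly and
  mirroring twice is the identity.
- **Determinism.** Every stochastic operation (noise, surface sampling)
  takes an explicit seed and restores the caller's RNG state; identical
  configs give byte-identical G-code and artifact checksums.

## Open design points, resolved

- The inversion ROI is an explicit user parameter (the original workflow's
  crop extent is not recoverable); `crater_roi()` provides it for phantoms.
- The 3-pixel median window is interpreted as a diameter (3³
  neighbourhood), not a radius.
- The 70 % volume scaling is isotropic about the volume centroid — the only
  convention that preserves shape and avoids translation surprises; the
  printed final dimensions alone cannot disambiguate the original
  convention.
- "50 % infill overlap" is read as infill lines extending into the innermost
  perimeter by half an extrusion width.
- The "fold change" between void sets is the ratio of total volumes
  (second over first).
- Retraction/combing are represented as plain travel moves; they carry no
  material and do not affect volume or geometry accounting.

## Problem sizes used in tests and the acceptance script

The validation suite runs the hemisphere wound phantom (20 mm deep crater in
a 28 mm limb) at the full 0.35 mm CT resolution — about 4.9 million voxels —
for shell thickness, placement, void recovery and conformality; coarser
0.7–0.9 mm phantoms exercise the bilateral and noisy-segmentation paths; the
slicer is validated on analytic primitives (cubes, spheres, cuboids) where
layer counts, spacings and fill fractions have closed forms. These sizes
were chosen so the full suite and the end-to-end demo complete in minutes on
a laptop while still exercising the study-resolution grid.

## Known limitations

- Single-threshold segmentation presumes bimodal contrast; multi-tissue or
  ML segmentation is out of scope.
- The slicer handles planar layers, perimeters and rectilinear infill only —
  no support material, acceleration planning, retraction tuning or
  firmware-specific dialects.
- Rigid registration only; the deformation of a soft patch during
  implantation is precisely what gauging is meant to *measure*, not model.
- Contact percentage implements the literal surface-area-ratio definition;
  wrinkled undersides can exceed 100 % and are reported as-is.
- Against the *analytic* crater surface, the voxel staircase bounds how
  close the designed underside can sit: about 98 % of the underside area is
  within half a voxel at 0.35 mm spacing (the suite asserts ≥ 95 % plus a
  one-voxel 99th percentile); against the segmented wound surface the
  underside is exactly coincident by construction.
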