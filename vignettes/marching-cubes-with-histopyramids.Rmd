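---
title: "Surface extraction from slice stacks: marching cubes with a histogram-pyramid index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface extraction from slice stacks: marching cubes with a histogram-pyramid index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histocubes)
```

## The problem

A CT or MRI study arrives as a stack of same-sized 2D grayscale slices. A
surface model of an anatomical structure — bone, airway, tumor boundary — is
the level set of the stacked 3D intensity field at a chosen threshold
(the *iso value*, in the 8-bit intensity units 0–255). `histocubes`
extracts that level set as a triangle mesh with the marching-cubes
algorithm, and accelerates the scan with a histogram pyramid that
enumerates only the cells that actually contribute geometry. Everything
needed to exercise the pipeline is generated internally by the phantom
module, so no clinical data is required.

## Marching cubes, as implemented here

Consecutive slices k and k + 1 are paired into a lattice of 2×2×2 cells:
a volume of `nx × ny × nz` voxels yields `(nx−1)(ny−1)(nz−1)` cells. Each
cell corner is classified against the iso value with the convention kept
verbatim from the classification this package follows:

* a corner with value **≥ iso is inner** and contributes bit 0,
* a corner with value **< iso is outer** and contributes bit 1,

so the eight corners form an 8-bit *cube index* with 2⁸ = 256 possible
configurations. Corner ids run 0–3 around the lower slice and 4–7 above,
with corner 6 the body-diagonal partner of corner 0; the twelve cell edges
are numbered e1–e4 (bottom ring), e5–e8 (top ring), e9–e12 (verticals).
These are the only assignments under which the two printed anchor facts
hold simultaneously: the bit pattern `01000001` (= 65, corners 0 and 6
outer) is the two-isolated-corners-on-a-body-diagonal configuration
(fundamental case 4), and it cuts exactly edges {1, 4, 9} and {6, 7, 12}.

```{r}
canonical_case(65)$case
intersected_edges(65)
```

Under the 24 cube rotations the 256 configurations collapse to 23 classes;
adding inner/outer complementation brings them to the classic 15
fundamental cases (`case_class_census()` recomputes both by brute-force
orbit enumeration). Case ids beyond the anchored case 4 follow the classic
enumeration by number of outer corners and their induced adjacency; the
full assignment is a repository convention recorded in
`canonical_case()`.

### The triangle table

The 256-entry table (one list of edge-id triangles per configuration) is
*generated*, not hand-typed: for each configuration the crossed edges on
each cube face are paired (two crossings pair directly; on an ambiguous
face — alternating corner signs — the two face edges incident to each
outer corner are paired), the pairings chain into closed polygons, each
polygon is oriented so its normal points from the inner toward the outer
region, and the polygon is fan-triangulated. Because the ambiguous-face
rule depends only on the face's own four corner signs, any two cells that
agree on a shared face cut it with the same segments — the table is
*face-consistent by construction*, so closed inputs always weld into
watertight meshes. This is a deliberate strengthening over generating
complementary entries by reusing a complementary triangulation, which is
known to admit topological holes across ambiguous faces; the
complement-symmetric *edge sets* (entries i and 255−i cross identical
edges) are preserved either way. The generated table also ships as a
plain-text file (`inst/extdata/mc_case_table.txt`) so other
implementations can diff it bit-exactly.

### Interpolation and welding

A crossed edge is cut at the linear interpolation point
`t = (iso − v_a)/(v_b − v_a)`, clamped to [0, 1]. Interpolation always
runs from the lexicographically lower lattice endpoint of the edge, so the
two cells sharing a lattice edge compute bit-identical coordinates; vertex
welding is then *exact integer identity* on the (lattice point, axis) key —
no floating-point tolerance anywhere. Welding never changes a triangle's
corner coordinates and never changes the triangle count; it only shares
storage. Degenerate triangles can arise only when the iso value equals a
lattice intensity exactly (t collapses to 0 or 1); they are dropped after
welding with a message. Triangle winding follows the right-hand rule with
normals pointing from the inner (≥ iso) region outward.

## The histogram pyramid

Cell classification is cheap; most cells produce nothing. The histogram
pyramid makes the sparsity explicit: level 0 stores each cell's triangle
count, every higher level halves each axis and stores the sum of its 2²
(2D) or 2³ (3D) children, and the single apex cell holds the total output
count M. The k-th output triangle is found by descending from the apex,
scanning the current cell's children in fixed x-fastest order and entering
the child whose half-open count range contains k — `log₂`(padded extent)
steps per query, the O(N) build + M·O(log N) traversal cost structure that
motivates the design. Compaction (`hp_compact()`) batches all M descents
level by level, and the extractor then emits exactly one triangle per
compacted (cell, offset) pair.

Two details are fixed as repository conventions:

* **Non-power-of-two grids** are zero-padded up to the next power of two;
  padded cells hold zero at every level and can never surface in a result.
* **Enumeration order** is the pyramid's intrinsic order — children
  scanned x-fastest at every level — which over the base grid is Z-order
  (Morton order), the natural order of any 2^d-ary count tree. It is
  block-consistent with row-major scanning at every scale but not globally
  identical to it; since the accelerated extractor's contract is
  *canonical-sorted equality* with the full scan, emission order is
  immaterial to the result.
* A **count pyramid** (per-cell triangle counts) is used rather than a
  0/1 active-cell flag pyramid: it is the stronger variant — the flag
  behavior is recovered by clamping counts to 1 — and it makes the output
  size known exactly before any geometry is allocated.

The worked 4×4 example with apex 8 reproduces the printed traversal:
output index 4 descends through ranges [0,8) → [3,5) → [4,5) (examining
and skipping [0,3) and [3,4) on the way) and lands on base cell (2, 1):

```{r}
counts <- t(matrix(c(2, 1, 0, 1,
                     0, 0, 1, 0,
                     1, 1, 0, 1,
                     0, 0, 0, 0), 4, 4, byrow = TRUE))
hp_traverse(hp_build(counts), 4)[c("cell", "offset")]
```

The defining contract of the accelerated extractor is that the
acceleration is invisible: `extract_mesh_hp()` equals
`extract_mesh_baseline()` bit for bit after canonical triangle sorting, on
every phantom and every iso value tested.

## Mesh metrics

**Mesh density** is the stored vertex count, the field's usual proxy when
comparing pipelines: an unwelded soup stores 3 vertices per triangle, a
welded mesh roughly half a vertex per triangle (V ≈ F/2 + 2 on a closed
genus-0 surface). Both counts are reported so either reading of a
density comparison can be evaluated.

**Roughness** is the mean over interior vertices of a local-window
(1-ring) curvature estimate:

κ̂(v) = 2 · |(v − mean of 1-ring neighbors) · n̂(v)| / (mean 1-ring edge length)²

with n̂ the area-weighted vertex normal. The projection onto the normal is
essential on extraction meshes: marching-cubes 1-rings are irregular, and
the raw umbrella displacement is dominated by its tangential component
(measured: ~0.73 against a true curvature of 0.05 on the r = 20 ramped
sphere; the normal-projected estimate gives 0.053). The estimator is 0 on
a plane, approaches 1/r on a sphere of radius r, and halves exactly when
the mesh is scaled by 2. Boundary and degree-< 3 vertices are excluded.
The estimator sits behind the `vertex_curvature()` interface so an
alternative (e.g. cotangent-weighted) can be swapped in without touching
callers. Stage timings are measured and reported in `metrics_report()`
but never asserted against — they are hardware-bound.

## Phantoms: what they emulate and what they do not

`sphere_volume()` and `torus_volume()` are binary (0/255) by default,
mimicking segmented CT masks; `noisy_volume()` adds seeded Gaussian voxel
noise (rounded and clamped so volumes stay 8-bit and slice stacks
round-trip exactly); `write_slice_stack()` emits zero-padded PNG slices so
lexicographic filename order is z order. The `ramp = TRUE` variants add a
1-voxel linear intensity ramp at the analytic boundary, giving edge
interpolation real sub-voxel information.

The distinction matters for accuracy statements. A *binary* phantom
carries no sub-voxel information: every crossing interpolates to the same
fixed fraction (128/255) of its edge, the mesh is a staircase-rounded
surface, and its area overestimates the analytic 4πr² by ≈ 9% at r = 20.
The *ramped* sphere reconstructs the analytic surface to ≈ 0.1% area
error. Accordingly, the 5%-area accuracy check runs on the ramped sphere
(the designated interpolation-accuracy fixture) while the binary sphere is
checked at its characteristic ≈ 9–15% band; topology checks
(watertightness, Euler characteristic 2 for the sphere, 0 for the torus)
hold for both. Passing on phantoms demonstrates correct geometry and
topology of the extraction on smooth, high-contrast objects; it says
nothing about partial-volume effects, anisotropic spacing, or the textured
noise of real reconstructions.

Default study conditions used throughout the acceptance-level suites:
sphere n = 64, r = 20; torus n = 64, R = 16, r_tube = 6 (a comparable
extent with an unambiguous genus-1 topology at this grid resolution);
noise sd = 20 with seed 1; iso ∈ {64, 128, 192}. Module tests use smaller
extents (n = 16–48) purely to keep the default test run quick; the
properties asserted are scale-free.

## Numerical choices and degenerate inputs

* Corners equal to the iso value are inner (≥), exactly as the
  classification is printed; an iso value outside the data range yields a
  warning plus a legitimate empty mesh, not an error.
* Cell visit order is fixed (z outer, y, x inner) and the whole pipeline
  is deterministic: identical inputs give bit-identical meshes.
* `lattice_point_count()` preserves the per-slice storage arithmetic
  `(fov + 1)²` of the storage scheme this package mirrors (320 → 103,041)
  even though the extraction lattice itself has `(n − 1)` cells per axis;
  the two conventions are deliberately both exposed rather than silently
  reconciled.
* Triangle indices are 1-based in memory (the R idiom); OBJ's 1-based and
  PLY/STL's 0-based conventions are translated only at the format
  boundary. Geometry lives in the 0-based voxel frame scaled by the voxel
  spacing.
* 8-bit grayscale PNG and PGM slices are supported (multi-channel images
  collapse by unweighted channel mean with a warning); whole volumes read
  from NRRD or MHD+raw headers. DICOM is out of scope — convert first.

## Known limitations

* Triangle quality is whatever marching cubes produces: thin triangles
  occur and no decimation or smoothing is applied (deliberately — the
  density comparison would otherwise be confounded).
* The curvature estimate is a 1-ring approximation, reliable in the mean
  but noisy per vertex on irregular extraction meshes (coefficient of
  variation ≈ 0.7 on a binary-phantom mesh vs ≈ 0.08 on a regular sphere
  triangulation).
* Anisotropic voxel spacing scales coordinates but the phantoms and
  accuracy statements assume isotropic lattices.
* Wall-clock comparisons between the two extractors are reported by the
  `compare` subcommand but depend entirely on volume sparsity and
  hardware; only mesh equality is guaranteed.
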