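# histocubes

Isosurface extraction from stacked 2D grayscale medical slices (CT/MRI),
in R: the marching-cubes algorithm with a histogram-pyramid index that
enumerates only the cells contributing geometry, plus shared-vertex
welding, OBJ/PLY/STL mesh I/O, mesh-density and curvature-roughness
metrics, deterministic sphere/torus phantoms, and a command-line front
end. It is written for image-analysis practitioners who need a
transparent, fully testable reference pipeline from slice stack to
watertight triangle mesh — no clinical data or GPU required.

## The method in brief

A volume of `nx × ny × nz` intensities (slices k and k + 1 paired along z)
is marched cell by cell. Each 2×2×2 cell's corners are classified against
the iso value `T`: corner value ≥ T is *inner* (bit 0), < T is *outer*
(bit 1), giving an 8-bit cube index with 2⁸ = 256 configurations that
reduce, under the 24 cube rotations plus inner/outer complementation, to
15 fundamental cases. A 256-entry table (generated, face-consistent,
shipped as plain text in `inst/extdata/mc_case_table.txt`) maps each index
to triangles whose vertices are linear interpolations
`t = (T − v_a)/(v_b − v_a)` along the crossed cell edges. Vertices
generated on the same lattice edge are welded by exact integer identity.

The accelerated path first stores each cell's triangle count in the base
of a *histogram pyramid* — every level halves each axis, parents hold the
sum of their 2³ children, the apex holds the total M — then resolves each
output index k to its cell in log₂ N steps and emits exactly M triangles:
O(N) build + M·O(log N) lookups, with the result guaranteed bit-identical
(after canonical sorting) to the full scan.

## Worked example

```r
library(histocubes)

v  <- sphere_volume(64, r = 20)        # binary ball phantom, intensities 0/255
mb <- extract_mesh_baseline(v, 128)    # full scan
mh <- extract_mesh_hp(v, 128)          # histogram-pyramid accelerated
mb
#> <mesh> 7584 vertices, 15164 triangles, with normals, lattice-edge keys attached

identical(canonical_triangles(mb), canonical_triangles(mh))
#> [1] TRUE

mesh_topology(mb)[c("euler", "watertight")]
#> $euler
#> [1] 2
#> $watertight
#> [1] TRUE

c(soup = mesh_density(extract_mesh_baseline(v, 128, weld = FALSE)),
  welded = mesh_density(mb))
#> soup welded
#> 45492   7584

write_mesh(mb, "sphere.obj")
```

Reading the output: the two extractors agree exactly (that equality is the
accelerated module's defining contract); the welded mesh is a closed
genus-0 surface (Euler characteristic V − E + F = 2, every edge in exactly
two triangles); welding shares each lattice-edge vertex once, collapsing
the 45,492 soup vertices (3 per triangle) to 7,584 — the mesh-density drop
that motivates vertex welding. Only 7,586 of the 250,047 cells (3%) are
active: the sparsity the pyramid exploits.

From a shell, the same pipeline:

```sh
Rscript inst/cli/histocubes.R phantom --shape sphere --n 64 --r 20 --out slices/
Rscript inst/cli/histocubes.R extract --slices slices/ --iso 128 \
    --method histopyramid --out sphere.obj     # + sphere.metrics.json
Rscript inst/cli/histocubes.R compare --slices slices/ --iso 128 --report cmp.json
```

(after installation the wrapper lives at
`system.file("cli", "histocubes.R", package = "histocubes")`).
Exit codes: 0 success, 2 usage, 3 I/O, 4 data error.

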