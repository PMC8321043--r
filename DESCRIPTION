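Package: histocubes
Title: Marching Cubes with Histogram-Pyramid Acceleration for Medical
    Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Isosurface extraction from stacked 2D grayscale medical slices
    (CT/MRI) by the marching-cubes algorithm, with a histogram-pyramid
    index that enumerates only the active cells so sparse volumes are
    compacted before any geometry is emitted. Includes shared-vertex
    welding, mesh readers/writers for OBJ, PLY and STL, mesh-density and
    curvature-roughness metrics, deterministic sphere/torus phantom
    generators, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
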