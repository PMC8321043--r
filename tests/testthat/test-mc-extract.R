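# Full-scan extraction: edge interpolation, welding, normals, topology.

test_that("interpolate_edge hits endpoints, midpoints, and is swap-invariant", {
  pa <- c(0, 0, 0); pb <- c(1, 0, 0)
  expect_equal(interpolate_edge(pa, pb, 50, 100, 50), pa)       # v_a == iso
  expect_equal(interpolate_edge(pa, pb, 0, 100, 50), c(0.5, 0, 0))
  expect_error(interpolate_edge(pa, pb, 10, 20, 50), class = "histocubes_data")
  set.seed(42)
  for (i in 1:50) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    v1 <- runif(1, 0, 100); v2 <- runif(1, 150, 250)
    iso <- runif(1, 101, 149)
    expect_equal(interpolate_edge(p1, p2, v1, v2, iso),
                 interpolate_edge(p2, p1, v2, v1, iso), tolerance = 1e-12)
  }
})

test_that("constant and out-of-range volumes give a legitimate empty mesh", {
  v <- volume(array(7, c(3, 3, 3)))
  expect_warning(m <- extract_mesh_baseline(v, 128), "empty")
  expect_identical(nrow(m$triangles), 0L)
  v2 <- sphere_volume(16, r = 5)
  expect_warning(m2 <- extract_mesh_baseline(v2, 300), "empty")
  expect_identical(nrow(m2$vertices), 0L)
})

test_that("a single hot voxel yields the closed 8-triangle corner surface", {
  vals <- array(0, c(3, 3, 3))
  vals[2, 2, 2] <- 255
  m <- extract_mesh_baseline(volume(vals), 128)
  tp <- mesh_topology(m)
  # octahedron around the center: 6 vertices, 12 edges, 8 faces, genus 0
  expect_identical(tp$F, 8L)
  expect_identical(tp$V, 6L)
  expect_identical(tp$E, 12L)
  expect_identical(tp$euler, 2L)
  expect_true(tp$watertight)
  # normals point away from the hot (inner) voxel at (1,1,1)
  centers <- (m$vertices[m$triangles[, 1], ] + m$vertices[m$triangles[, 2], ] +
                m$vertices[m$triangles[, 3], ]) / 3
  outward <- centers - matrix(1, nrow(centers), 3)
  expect_true(all(rowSums(outward * m$normals) > 0))
})

test_that("welding shares lattice-edge vertices without touching geometry", {
  v <- sphere_volume(24, r = 8)
  soup <- extract_mesh_baseline(v, 128, weld = FALSE)
  welded <- weld_vertices(soup)
  expect_lt(nrow(welded$vertices), nrow(soup$vertices))
  expect_identical(nrow(welded$triangles), nrow(soup$triangles))
  # per-triangle corner coordinates identical before/after
  for (k in 1:3)
    expect_identical(welded$vertices[welded$triangles[, k], ],
                     soup$vertices[soup$triangles[, k], ])
  # idempotent
  expect_identical(weld_vertices(welded), welded)
  # no degenerate triangles, and the closed genus-0 relation V = F/2 + 2
  tr <- welded$triangles
  expect_false(any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
  m <- extract_mesh_baseline(v, 128)
  expect_identical(nrow(m$vertices), nrow(m$triangles) %/% 2L + 2L)
  # two adjacent cells cut around one shared inner corner: each emits one
  # corner triangle (6 soup vertices); the 2 cut edges lying in the shared
  # face are stored once each, leaving 4 welded vertices
  vals <- array(0, c(3, 2, 2))
  vals[2, 1, 1] <- 255
  soup2 <- extract_mesh_baseline(volume(vals), 128, weld = FALSE)
  expect_identical(nrow(soup2$vertices), 6L)
  w2 <- weld_vertices(soup2)
  expect_identical(nrow(w2$vertices), 4L)
})

test_that("triangle normals obey the right-hand rule and unit length", {
  m <- mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_equal(triangle_normals(m), rbind(c(0, 0, 1)))
  m_rev <- mesh(m$vertices, rbind(c(1, 3, 2)))
  expect_equal(triangle_normals(m_rev), rbind(c(0, 0, -1)))
  degen <- mesh(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), rbind(1:3))
  expect_error(triangle_normals(degen), "triangle", class = "histocubes_data")
  # sphere phantom: normals near the outward radial direction
  v <- sphere_volume(32, r = 10)
  ms <- extract_mesh_baseline(v, 128)
  centers <- (ms$vertices[ms$triangles[, 1], ] + ms$vertices[ms$triangles[, 2], ] +
                ms$vertices[ms$triangles[, 3], ]) / 3
  radial <- centers - matrix(15.5, nrow(centers), 3)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_gt(mean(rowSums(radial * ms$normals)), 0.9)
})

test_that("triangle count grows with phantom radius and runs are bit-identical", {
  v <- sphere_volume(48, r = 10)
  counts <- vapply(c(5, 10, 15, 20), function(r)
    nrow(extract_mesh_baseline(sphere_volume(48, r = r), 128)$triangles),
    integer(1))
  expect_true(all(diff(counts) >= 0))
  m1 <- extract_mesh_baseline(v, 128)
  m2 <- extract_mesh_baseline(v, 128)
  expect_identical(m1, m2)
})

test_that("an iso value equal to lattice intensities drops collapsed triangles", {
  vals <- array(0, c(3, 3, 3))
  vals[2, 2, 2] <- 128
  # iso exactly at the hot value: crossings interpolate onto lattice points
  expect_message(m <- extract_mesh_baseline(volume(vals), 128),
                 "degenerate")
  tr <- m$triangles
  if (nrow(tr))
    expect_false(any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] |
                       tr[, 1] == tr[, 3]))
})
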