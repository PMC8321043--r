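# Slice-stack and raw-volume reading, storage arithmetic.

test_that("constant slice stack reads back exactly", {
  dir <- withr::local_tempdir()
  v <- volume(array(7, c(2, 2, 2)))
  paths <- write_slice_stack(v, dir)
  expect_length(paths, 2L)
  got <- read_slice_stack(paths)
  expect_equal(got$values, v$values)
  expect_equal(got$intensity_range, c(7, 7))
})

test_that("slice stacks preserve every scalar and are order-sensitive", {
  dir <- withr::local_tempdir()
  set.seed(11)
  v <- volume(array(sample(0:255, 16 * 12 * 4, replace = TRUE), c(16, 12, 4)))
  paths <- write_slice_stack(v, dir)
  expect_identical(basename(paths),
                   sprintf("slice_%04d.png", 0:3))        # lexicographic = z
  expect_equal(read_slice_stack(paths)$values, v$values)
  perm <- c(3, 1, 4, 2)
  permuted <- read_slice_stack(paths[perm])
  expect_equal(permuted$values, v$values[, , perm])
})

test_that("malformed stacks raise classed errors", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 2, 2), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 3, 3), file.path(dir, "b.png"))
  expect_error(read_slice_stack(file.path(dir, c("a.png", "b.png"))),
               "b.png", class = "histocubes_data")
  expect_error(read_slice_stack(file.path(dir, "a.png")),
               class = "histocubes_data")
  expect_error(read_slice_stack(file.path(dir, c("a.png", "missing.png"))),
               class = "histocubes_io")
})

test_that("PGM slices (binary and ASCII) read like PNG slices", {
  dir <- withr::local_tempdir()
  m <- matrix(as.integer(c(0, 64, 128, 255, 1, 2)), nrow = 3)  # 3 x 2
  p5 <- file.path(dir, "s0.pgm")
  con <- file(p5, "wb")
  writeLines(c("P5", "# comment", "3 2", "255"), con)
  writeBin(as.raw(as.vector(m)), con)   # row-major: x fastest
  close(con)
  p2 <- file.path(dir, "s1.pgm")
  writeLines(c("P2", "3 2", "255", paste(as.vector(m), collapse = " ")), p2)
  v <- read_slice_stack(c(p5, p2))
  expect_equal(dim(v$values), c(3L, 2L, 2L))
  expect_equal(v$values[, , 1], v$values[, , 2])
  expect_equal(v$values[, , 1][, 1], c(0, 64, 128))
})

test_that("multi-channel slices collapse by channel mean with a warning", {
  dir <- withr::local_tempdir()
  rgb <- array(rep(c(1, 102/255, 0), each = 4), c(2, 2, 3))  # constant per channel
  png::writePNG(rgb, file.path(dir, "a.png"))
  png::writePNG(rgb, file.path(dir, "b.png"))
  w <- capture_warnings(
    v <- read_slice_stack(file.path(dir, c("a.png", "b.png"))))
  expect_match(w, "channel mean", all = TRUE)
  expect_length(w, 2)   # one warning per converted slice
  expect_equal(v$values[1, 1, 1], mean(c(255, 102, 0)))
})

test_that("lattice_point_count reproduces the per-slice storage arithmetic", {
  expect_equal(lattice_point_count(320), 103041)
  expect_equal(lattice_point_count(1), 4)
  expect_equal(lattice_point_count(127), 16384)
  expect_error(lattice_point_count(0), class = "histocubes_data")
  fovs <- 1:50
  counts <- vapply(fovs, lattice_point_count, numeric(1))
  expect_true(all(diff(counts) > 0))       # strictly increasing
})

test_that("NRRD and MHD raw volumes read back exactly", {
  dir <- withr::local_tempdir()
  set.seed(3)
  vals <- array(sample(0:255, 5 * 4 * 3, replace = TRUE), c(5, 4, 3))
  # NRRD, raw encoding
  nrrd <- file.path(dir, "v.nrrd")
  con <- file(nrrd, "wb")
  writeLines(c("NRRD0004", "type: uchar", "dimension: 3", "sizes: 5 4 3",
               "spacings: 1 1 2", "encoding: raw", ""), con)
  writeBin(as.raw(as.vector(vals)), con)
  close(con)
  v1 <- read_volume(nrrd)
  expect_equal(v1$values, vals + 0)
  expect_equal(v1$spacing, c(1, 1, 2))
  # NRRD, text encoding
  nrrd2 <- file.path(dir, "v2.nrrd")
  writeLines(c("NRRD0004", "type: float", "dimension: 3", "sizes: 5 4 3",
               "encoding: text", "", paste(as.vector(vals), collapse = " ")),
             nrrd2)
  expect_equal(read_volume(nrrd2)$values, vals + 0)
  # MHD + raw
  mhd <- file.path(dir, "v.mhd")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 5 4 3",
               "ElementType = MET_UCHAR", "ElementSpacing = 1 1 1",
               "ElementDataFile = v.raw"), mhd)
  writeBin(as.raw(as.vector(vals)), file.path(dir, "v.raw"))
  expect_equal(read_volume(mhd)$values, vals + 0)
  # truncated raw block
  writeBin(as.raw(as.vector(vals))[1:10], file.path(dir, "v.raw"))
  expect_error(read_volume(mhd), "truncated", class = "histocubes_io")
})

test_that("volume constructor enforces its invariants", {
  expect_error(volume(array(1, c(1, 4, 4))), class = "histocubes_data")
  expect_error(volume(array(c(NA, rep(1, 7)), c(2, 2, 2))),
               class = "histocubes_data")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               class = "histocubes_data")
  v <- volume(array(0:7, c(2, 2, 2)), spacing = c(0.5, 0.5, 2))
  expect_equal(v$intensity_range, c(0, 7))
  expect_equal(prod(dim(v$values)), 8)
})
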