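# Cube conventions, index construction, the 256-entry table and its
# canonicalization onto the 15 fundamental configurations.

test_that("corner and edge conventions match the documented incidences", {
  co <- mc_corner_offsets()
  expect_equal(unname(co[1, ]), c(0L, 0L, 0L))
  expect_equal(unname(co[7, ]), c(1L, 1L, 1L))   # corner 6 opposite corner 0
  ee <- mc_edge_endpoints()
  incident <- function(c0) which(ee[, 1] == c0 | ee[, 2] == c0)
  expect_setequal(incident(0), c(1, 4, 9))
  expect_setequal(incident(6), c(6, 7, 12))
  # 12 distinct geometric edges: endpoints differ in exactly one coordinate
  expect_equal(nrow(unique(cbind(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2])))), 12L)
  hamming <- rowSums(abs(co[ee[, 1] + 1, ] - co[ee[, 2] + 1, ]))
  expect_true(all(hamming == 1))
})

test_that("cube_index uses the printed polarity (1 = outer, < iso)", {
  expect_identical(cube_index(rep(200, 8), 128), 0L)     # all inner
  expect_identical(cube_index(rep(5, 8), 128), 255L)     # all outer
  # corners 0 and 6 below iso, rest above: binary 01000001 = 65
  vals <- rep(255, 8)
  vals[c(1, 7)] <- 0
  expect_identical(cube_index(vals, 128), 65L)
  # a corner equal to iso is inner (>= iso), so contributes bit 0
  expect_identical(cube_index(c(128, rep(255, 7)), 128), 0L)
  expect_error(cube_index(c(NA, rep(1, 7)), 128), class = "histocubes_data")
  # every one of the 256 configurations is realizable
  for (i in c(0:7, 64:66, 254:255)) {
    bits <- bitwAnd(bitwShiftR(i, 0:7), 1L)
    expect_identical(cube_index(ifelse(bits == 1, 0, 255), 128), i)
  }
})

test_that("canonicalization reproduces the worked case and the class census", {
  expect_identical(canonical_case(0)$case, 0L)
  expect_identical(canonical_case(65)$case, 4L)      # two body-diagonal corners
  c255 <- canonical_case(255)
  expect_identical(c255$case, 0L)
  expect_true(c255$complement)
  census <- case_class_census()
  expect_identical(census$rotation_only, 23L)
  expect_identical(census$rotation_complement, 15L)
  # total over 0..255, all 15 cases hit
  cases <- vapply(0:255, function(i) canonical_case(i)$case, integer(1))
  expect_setequal(cases, 0:14)
  # the recorded transform actually maps the representative onto the index
  reps <- vapply(0:14, function(cs) {
    idxs <- which(cases == cs) - 1L
    idxs[which.min(vapply(idxs, function(i)
      sum(bitwAnd(bitwShiftR(i, 0:7), 1L)), integer(1)))]
  }, integer(1))
  for (i in c(0:10, 65, 100:110, 200, 255)) {
    tr <- canonical_case(i)
    rep_idx <- reps[tr$case + 1L]
    bits <- bitwAnd(bitwShiftR(rep_idx, 0:7), 1L)
    moved <- integer(8)
    moved[tr$rotation + 1L] <- bits
    img <- sum(moved * 2^(0:7))
    if (tr$complement) img <- 255 - img
    expect_identical(as.integer(img), as.integer(i))
  }
})

test_that("intersected_edges matches bit-straddling and the worked example", {
  expect_identical(intersected_edges(0), integer(0))
  expect_setequal(intersected_edges(65), c(1, 4, 9, 6, 7, 12))
  ee <- mc_edge_endpoints()
  for (i in 0:255) {
    bits <- bitwAnd(bitwShiftR(i, 0:7), 1L)
    expect_identical(intersected_edges(i),
                     which(bits[ee[, 1] + 1] != bits[ee[, 2] + 1]))
    # complement symmetry
    expect_identical(intersected_edges(i), intersected_edges(255 - i))
  }
})

test_that("the triangle table is complete and uses exactly the crossed edges", {
  tt <- mc_triangle_table()
  expect_length(tt, 256L)
  expect_identical(nrow(tt[[1]]), 0L)
  expect_identical(nrow(tt[[256]]), 0L)
  for (i in 0:255) {
    used <- unique(as.vector(tt[[i + 1]]))
    expect_setequal(used, intersected_edges(i))
  }
  # the worked configuration cuts two corner triangles
  e65 <- tt[[66]]
  expect_identical(nrow(e65), 2L)
  expect_setequal(as.vector(e65[1, ]), if (1 %in% e65[1, ]) c(1, 4, 9) else c(6, 7, 12))
})

test_that("shipped plain-text case table matches the generated one", {
  path <- system.file("extdata", "mc_case_table.txt", package = "histocubes")
  expect_true(nzchar(path))
  expect_identical(readLines(path), histocubes:::.hc_table_text())
})

test_that("triangulations of face-adjacent configurations meet edge to edge", {
  # For each axis, any two configurations that agree on the shared face must
  # cut that face with the same segment set; otherwise welded meshes from
  # adjacent cells would leak. Checked by brute force over all 256 x 256
  # agreeing pairs per axis.
  ee <- mc_edge_endpoints()
  co <- mc_corner_offsets()
  tt <- mc_triangle_table()
  face_corners <- function(axis, side)
    which(co[, axis] == side) - 1L          # corner ids on that face
  edge_on_face <- function(axis, side) {
    onf <- co[ee[, 1] + 1, axis] == side & co[ee[, 2] + 1, axis] == side
    which(onf)
  }
  # segments of entry i lying on the given face, as sorted edge-id pairs,
  # keeping odd multiplicity only (even = internal fan diagonals)
  face_segments <- function(i, fe) {
    tr <- tt[[i + 1]]
    if (!nrow(tr)) return(character(0))
    segs <- character(0)
    for (r in seq_len(nrow(tr))) for (k in 1:3) {
      a <- tr[r, k]; b <- tr[r, (k %% 3) + 1]
      if (a %in% fe && b %in% fe)
        segs <- c(segs, paste(sort(c(a, b)), collapse = "-"))
    }
    tb <- table(segs)
    sort(names(tb)[tb %% 2 == 1])
  }
  for (axis in 1:3) {
    hiC <- face_corners(axis, 1)            # A's high face
    loC <- face_corners(axis, 0)            # B's low face
    hiE <- edge_on_face(axis, 1)
    loE <- edge_on_face(axis, 0)
    # match corners/edges across the shared plane by their in-plane coords
    other <- setdiff(1:3, axis)
    ckey <- function(ids, side) apply(co[ids + 1, other, drop = FALSE], 1,
                                      paste, collapse = ",")
    cmap <- loC[match(ckey(hiC), ckey(loC))]          # A corner -> B corner
    ekey <- function(eids, side) {
      a <- co[ee[eids, 1] + 1, other, drop = FALSE]
      b <- co[ee[eids, 2] + 1, other, drop = FALSE]
      apply(cbind(pmin(a, b), pmax(a, b)), 1, paste, collapse = ",")
    }
    emap <- integer(12)
    emap[hiE] <- loE[match(ekey(hiE), ekey(loE))]     # A edge -> B edge
    bad <- 0L
    for (ia in 0:255) {
      ba <- bitwAnd(bitwShiftR(ia, 0:7), 1L)
      pa <- face_segments(ia, hiE)
      if (!length(pa)) next
      pa_mapped <- sort(vapply(strsplit(pa, "-"), function(s) {
        e <- sort(emap[as.integer(s)])
        paste(e, collapse = "-")
      }, character(1)))
      fa <- ba[hiC + 1]
      for (ib in 0:255) {
        bb <- bitwAnd(bitwShiftR(ib, 0:7), 1L)
        if (!all(fa == bb[cmap + 1])) next
        if (!identical(pa_mapped, face_segments(ib, loE))) bad <- bad + 1L
      }
    }
    expect_identical(bad, 0L)
  }
})
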