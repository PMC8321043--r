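# Cube conventions, the 256-entry marching-cubes case table, and
# canonicalization onto the 15 fundamental configurations.
#
# Conventions (fixed for the whole package):
#   * Corner ids 0-7: bottom ring 0,1,2,3 (z = 0, counterclockwise from the
#     origin), top ring 4,5,6,7 stacked above; corner 6 = (1,1,1) is the
#     body-diagonal partner of corner 0 = (0,0,0).
#   * Edge ids 1-12: bottom ring e1-e4, top ring e5-e8, verticals e9-e12.
#     Corner 0 is incident to e1, e4, e9; corner 6 to e6, e7, e12.
#   * Cube-index polarity: bit b is 1 when corner b is OUTER (value < iso),
#     0 when INNER (value >= iso). Index 0 therefore means "all inside".

#' Corner offsets of the unit cube
#'
#' Returns the 8 x 3 matrix of corner offsets, one row per corner id 0-7,
#' each offset in \{0,1\}^3 (columns x, y, z). Corner 0 is the cell origin,
#' corner 6 its body-diagonal partner.
#'
#' @return Integer matrix with 8 rows (corners 0-7) and columns x, y, z.
#' @export
#' @examples
#' mc_corner_offsets()
mc_corner_offsets <- function() {
  m <- rbind(
    c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
    c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  dimnames(m) <- list(corner = 0:7, c("x", "y", "z"))
  m
}

#' Edge endpoints of the unit cube
#'
#' Returns the 12 x 2 matrix of corner-id pairs, one row per edge id 1-12:
#' bottom ring e1-e4, top ring e5-e8, verticals e9-e12.
#'
#' @return Integer matrix with 12 rows (edges 1-12), corner ids 0-7.
#' @export
#' @examples
#' mc_edge_endpoints()[c(1, 4, 9), ]  # the three edges at corner 0
mc_edge_endpoints <- function() {
  m <- rbind(
    c(0L, 1L), c(1L, 2L), c(2L, 3L), c(3L, 0L),
    c(4L, 5L), c(5L, 6L), c(6L, 7L), c(7L, 4L),
    c(0L, 4L), c(1L, 5L), c(3L, 7L), c(2L, 6L))
  dimnames(m) <- list(edge = 1:12, c("a", "b"))
  m
}

# faces as cyclic corner sequences; face edge i joins cyclic corners i, i+1
.hc_faces <- list(
  c(0L, 1L, 2L, 3L), c(4L, 5L, 6L, 7L), c(0L, 1L, 5L, 4L),
  c(1L, 2L, 6L, 5L), c(2L, 3L, 7L, 6L), c(3L, 0L, 4L, 7L))

# per edge id: offset of the lexicographically lower lattice endpoint and the
# axis (1 = x, 2 = y, 3 = z) along which the edge runs; fixes the canonical
# interpolation direction so both cells sharing a lattice edge compute the
# identical vertex bit for bit
.hc_edge_base <- rbind(
  c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 0L),
  c(0L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L), c(0L, 0L, 1L),
  c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L))
.hc_edge_axis <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 3L, 3L, 3L, 3L)

# package-local cache for the derived tables
.hc_cache <- new.env(parent = emptyenv())

# the 24 orientation-preserving symmetries as corner permutations:
# column r gives, for each corner id 0-7 (row), its image under rotation r
.hc_rotation_perms <- function() {
  if (!is.null(.hc_cache$rot)) return(.hc_cache$rot)
  co <- mc_corner_offsets()
  perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  rot <- matrix(NA_integer_, 8, 24)
  r <- 0L
  for (p in seq_len(6)) for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
    M <- matrix(0, 3, 3)
    s <- c(sx, sy, sz)
    for (i in 1:3) M[i, perms3[p, i]] <- s[i]
    if (abs(det(M) - 1) > 1e-9) next
    r <- r + 1L
    img <- apply(co, 1, function(v) {
      w <- as.vector(M %*% (v - 0.5)) + 0.5
      which(colSums(abs(t(co) - w)) < 1e-9) - 1L
    })
    rot[, r] <- img
  }
  .hc_cache$rot <- rot
  rot
}

.hc_rotate_index <- function(idx, perm) {
  bits <- bitwAnd(bitwShiftR(idx, 0:7), 1L)
  nb <- integer(8)
  nb[perm + 1L] <- bits
  as.integer(sum(nb * 2^(0:7)))
}

# representatives of the 15 fundamental configurations, indexed case 0-14.
# Case 4 ({corners 2,4}: a body-diagonal pair) is anchored by the printed
# worked example (index 01000001 -> case 4); the remaining ids follow the
# classic enumeration by number of outer corners and induced adjacency.
.hc_case_reps <- c(0L, 1L, 3L, 5L, 20L, 7L, 21L, 26L,
                   15L, 23L, 60L, 29L, 27L, 90L, 30L)

.hc_case_map <- function() {
  if (!is.null(.hc_cache$case_map)) return(.hc_cache$case_map)
  rot <- .hc_rotation_perms()
  case_of <- rep(NA_integer_, 256)
  rot_of <- rep(NA_integer_, 256)
  comp_of <- rep(NA, 256)
  for (case_id in seq_along(.hc_case_reps) - 1L) {
    rep_idx <- .hc_case_reps[case_id + 1L]
    for (r in 1:24) {
      for (comp in c(FALSE, TRUE)) {
        src <- .hc_rotate_index(rep_idx, rot[, r])
        if (comp) src <- 255L - src
        # rotation r maps rep -> src; record inverse direction lazily
        if (is.na(case_of[src + 1L])) {
          case_of[src + 1L] <- case_id
          rot_of[src + 1L] <- r
          comp_of[src + 1L] <- comp
        }
      }
    }
  }
  stopifnot(!anyNA(case_of))
  .hc_cache$case_map <- list(case = case_of, rotation = rot_of, complement = comp_of)
  .hc_cache$case_map
}

#' Cube index from the eight corner values
#'
#' Builds the 8-bit configuration code of one cell: bit b is 1 when corner b
#' is outer (value strictly below the iso threshold) and 0 when inner (value
#' greater than or equal to the threshold). All 2^8 = 256 codes can arise.
#'
#' @param corner_values Numeric vector of length 8, corner order 0-7.
#' @param iso Iso threshold in intensity units.
#' @return Integer in 0-255.
#' @export
#' @examples
#' cube_index(rep(200, 8), 128)                    # all inner -> 0
#' cube_index(c(0, rep(255, 5), 0, 255), 128)      # corners 0 and 6 outer -> 65
cube_index <- function(corner_values, iso) {
  if (length(corner_values) != 8L)
    .hc_stop("corner_values must have length 8", "data")
  if (!all(is.finite(corner_values)) || !is.finite(iso))
    .hc_stop("cube_index requires finite corner values and iso", "data")
  as.integer(sum((corner_values < iso) * 2^(0:7)))
}

#' Edges crossed by the isosurface for a cube configuration
#'
#' An edge is crossed exactly when its two endpoint corners carry different
#' bits of the configuration code, i.e. one endpoint is inner and the other
#' outer.
#'
#' @param index Integer cube index in 0-255.
#' @return Sorted integer vector of edge ids (1-12).
#' @export
#' @examples
#' intersected_edges(65)  # the worked two-opposite-corners case
intersected_edges <- function(index) {
  index <- .hc_check_index(index)
  bits <- bitwAnd(bitwShiftR(index, 0:7), 1L)
  ee <- mc_edge_endpoints()
  which(bits[ee[, 1] + 1L] != bits[ee[, 2] + 1L])
}

#' Canonicalize a cube configuration onto the 15 fundamental cases
#'
#' Every one of the 256 corner configurations reduces, under the 24 cube
#' rotations plus inner/outer complementation, to one of 15 fundamental
#' cases (and to one of 23 classes under rotations alone). Case ids follow
#' the classic enumeration; case 4 is the two-isolated-corners-on-a-body-
#' diagonal configuration.
#'
#' @param index Integer cube index in 0-255.
#' @return List with elements \code{case} (0-14), \code{rotation} (corner
#'   permutation, an integer vector of length 8 mapping the case
#'   representative's corners onto \code{index}'s corners), and
#'   \code{complement} (logical; whether inner/outer must also be swapped).
#' @export
#' @examples
#' canonical_case(65)$case   # 4
#' canonical_case(255)$case  # 0, via complement
canonical_case <- function(index) {
  index <- .hc_check_index(index)
  cm <- .hc_case_map()
  rot <- .hc_rotation_perms()
  list(case = cm$case[index + 1L],
       rotation = rot[, cm$rotation[index + 1L]],
       complement = cm$complement[index + 1L])
}

#' Number of configuration classes under cube symmetries
#'
#' Brute-force orbit census of the 256 cube configurations: under the 24
#' rotations alone, and under rotations plus inner/outer complementation.
#'
#' @return List with integer elements \code{rotation_only} and
#'   \code{rotation_complement}.
#' @export
#' @examples
#' case_class_census()  # 23 and 15
case_class_census <- function() {
  rot <- .hc_rotation_perms()
  orbit_count <- function(use_complement) {
    seen <- rep(FALSE, 256)
    n <- 0L
    for (i in 0:255) {
      if (seen[i + 1L]) next
      n <- n + 1L
      frontier <- i
      seen[i + 1L] <- TRUE
      while (length(frontier)) {
        nxt <- integer(0)
        for (j in frontier) {
          imgs <- vapply(1:24, function(r) .hc_rotate_index(j, rot[, r]), integer(1))
          if (use_complement) imgs <- c(imgs, 255L - j)
          for (m in imgs) if (!seen[m + 1L]) {
            seen[m + 1L] <- TRUE
            nxt <- c(nxt, m)
          }
        }
        frontier <- nxt
      }
    }
    n
  }
  list(rotation_only = orbit_count(FALSE),
       rotation_complement = orbit_count(TRUE))
}

# Build one table entry by face-walking: pair the crossed edges on each face
# (on an ambiguous face, pair the two face edges incident to each outer
# corner, a fixed rule applied identically everywhere so that the pairing of
# a shared face is decided by the face's own bits alone), chain the pairings
# into closed polygons, orient each polygon so its normal points from the
# inner (>= iso) toward the outer (< iso) region, and fan-triangulate.
.hc_build_entry <- function(idx) {
  co <- mc_corner_offsets()
  ee <- mc_edge_endpoints()
  bits <- bitwAnd(bitwShiftR(idx, 0:7), 1L)
  crossed <- which(bits[ee[, 1] + 1L] != bits[ee[, 2] + 1L])
  if (!length(crossed)) return(matrix(integer(0), 0, 3))
  adjl <- vector("list", 12)
  for (f in .hc_faces) {
    fe <- vapply(1:4, function(i) {
      a <- f[i]; b <- f[(i %% 4) + 1]
      which(ee[, 1] == pmin(a, b) & ee[, 2] == pmax(a, b) |
            ee[, 1] == pmax(a, b) & ee[, 2] == pmin(a, b))
    }, integer(1))
    fb <- bits[f + 1L]
    cr <- which(fb != fb[c(2, 3, 4, 1)])
    add_pair <- function(p, q) {
      adjl[[p]] <<- c(adjl[[p]], q)
      adjl[[q]] <<- c(adjl[[q]], p)
    }
    if (length(cr) == 2) {
      add_pair(fe[cr[1]], fe[cr[2]])
    } else if (length(cr) == 4) {
      for (ci in which(fb == 1L)) add_pair(fe[((ci - 2) %% 4) + 1], fe[ci])
    }
  }
  mids <- (co[ee[, 1] + 1L, ] + co[ee[, 2] + 1L, ]) / 2
  seen <- rep(FALSE, 12)
  tris <- matrix(integer(0), 0, 3)
  for (st in crossed) {
    if (seen[st]) next
    cyc <- st
    seen[st] <- TRUE
    cur <- st
    prv <- 0L
    repeat {
      nxts <- adjl[[cur]]
      nxt <- if (nxts[1] != prv) nxts[1] else nxts[2]
      if (nxt == st) break
      cyc <- c(cyc, nxt)
      seen[nxt] <- TRUE
      prv <- cur
      cur <- nxt
    }
    pts <- mids[cyc, , drop = FALSE]
    nrm <- c(0, 0, 0)
    np <- nrow(pts)
    for (i in seq_len(np)) {           # Newell normal of the polygon
      j <- (i %% np) + 1
      nrm <- nrm + c((pts[i, 2] - pts[j, 2]) * (pts[i, 3] + pts[j, 3]),
                     (pts[i, 3] - pts[j, 3]) * (pts[i, 1] + pts[j, 1]),
                     (pts[i, 1] - pts[j, 1]) * (pts[i, 2] + pts[j, 2]))
    }
    dirv <- c(0, 0, 0)                 # mean inner -> outer direction
    for (e in cyc) {
      a <- ee[e, 1] + 1L
      b <- ee[e, 2] + 1L
      if (bits[a] == 1L) dirv <- dirv + (co[a, ] - co[b, ])
      else dirv <- dirv + (co[b, ] - co[a, ])
    }
    if (sum(nrm * dirv) < 0) cyc <- rev(cyc)
    for (i in 2:(length(cyc) - 1))
      tris <- rbind(tris, cyc[c(1L, i, i + 1L)])
  }
  storage.mode(tris) <- "integer"
  tris
}

#' The full 256-entry triangle table
#'
#' Returns the case table used by both extractors: for each cube index
#' 0-255, the triangles the isosurface cuts out of that cell, given as
#' ordered edge-id triples (winding such that the right-hand-rule normal
#' points from the inner toward the outer region). Entries 0 and 255 are
#' empty. The same table ships as a plain-text file under
#' \code{system.file("extdata", "mc_case_table.txt", package = "histocubes")}
#' so that other implementations can diff it bit-exactly.
#'
#' @return List of 256 integer matrices (one per index 0-255), each with 3
#'   columns of edge ids.
#' @export
#' @examples
#' mc_triangle_table()[[65 + 1]]  # two triangles: edges 1,4,9 and 6,7,12
mc_triangle_table <- function() {
  if (is.null(.hc_cache$tri_table))
    .hc_cache$tri_table <- lapply(0:255, .hc_build_entry)
  .hc_cache$tri_table
}

# serialize the table in the shipped text format:
# "<index>: e e e; e e e; ..." (or "<index>:" for empty entries)
.hc_table_text <- function() {
  vapply(0:255, function(i) {
    tr <- mc_triangle_table()[[i + 1L]]
    if (!nrow(tr)) return(sprintf("%d:", i))
    sprintf("%d: %s", i,
            paste(apply(tr, 1, paste, collapse = " "), collapse = "; "))
  }, character(1))
}

.hc_check_index <- function(index) {
  if (length(index) != 1L || !is.finite(index) || index < 0 || index > 255 ||
      index != round(index))
    .hc_stop("cube index must be a single integer in 0..255", "data")
  as.integer(index)
}
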