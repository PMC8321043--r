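# Shared fixtures: analytic meshes built directly (not via extraction) and
# an independent prefix-sum oracle for pyramid compaction.

# regular longitude/latitude sphere mesh of radius r (poles omitted, so the
# two polar rows are boundary vertices and drop out of curvature averages)
uv_sphere_mesh <- function(r = 20, nth = 40, nph = 80) {
  th <- seq(0, pi, length.out = nth)[-c(1, nth)]
  gr <- expand.grid(th = th, ph = seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)])
  pts <- r * cbind(sin(gr$th) * cos(gr$ph), sin(gr$th) * sin(gr$ph), cos(gr$th))
  nr <- nth - 2
  idx <- function(i, j) (j - 1) * nr + i
  tris <- vector("list", nph * (nr - 1) * 2)
  k <- 0
  for (j in 1:nph) {
    jn <- (j %% nph) + 1
    for (i in 1:(nr - 1)) {
      tris[[k <- k + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, jn))
      tris[[k <- k + 1]] <- c(idx(i + 1, j), idx(i + 1, jn), idx(i, jn))
    }
  }
  mesh(pts, do.call(rbind, tris))
}

# flat triangulated grid patch in the z = 0 plane
flat_patch_mesh <- function(nx = 10, ny = 10) {
  gx <- expand.grid(x = 0:nx, y = 0:ny)
  idx <- function(i, j) j * (nx + 1) + i + 1
  tris <- vector("list", nx * ny * 2)
  k <- 0
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    tris[[k <- k + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
    tris[[k <- k + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  mesh(cbind(gx$x, gx$y, 0), do.call(rbind, tris))
}

# the 4x4 base-count grid whose pyramid reproduces the printed worked
# example: apex 8, level-1 block ranges [0,3) [3,5) [5,7) [7,8), and
# output index 4 resolving to cell (2, 1)
worked_example_counts <- function() {
  t(matrix(c(2, 1, 0, 1,
             0, 0, 1, 0,
             1, 1, 0, 1,
             0, 0, 0, 0), 4, 4, byrow = TRUE))  # [x, y] indexing
}

# independent oracle for hp_compact: expand base counts cell by cell in the
# pyramid's enumeration order (Morton/Z-order, x fastest), computed here by
# explicit bit interleaving with no pyramid involved
morton_rank <- function(coords, bits = 10L) {
  d <- ncol(coords)
  r <- numeric(nrow(coords))
  for (b in 0:(bits - 1)) for (ax in seq_len(d))
    r <- r + bitwAnd(bitwShiftR(coords[, ax], b), 1L) * 2^(b * d + (ax - 1))
  r
}

oracle_compact <- function(counts) {
  d <- dim(counts)
  coords <- as.matrix(do.call(expand.grid, lapply(d, function(n) 0:(n - 1))))
  colnames(coords) <- NULL
  ord <- order(morton_rank(coords))
  coords <- coords[ord, , drop = FALSE]
  cnt <- as.vector(counts)[ord]
  keep <- cnt > 0
  list(cells = coords[rep(which(keep), cnt[keep]), , drop = FALSE],
       offsets = as.integer(sequence(cnt[keep]) - 1L))
}

# seeded random count grid (2D or 3D), non-power-of-two extents included
random_count_grid <- function(seed, d3 = FALSE) {
  set.seed(seed)
  dims <- if (d3) sample(2:6, 3, replace = TRUE) else sample(2:9, 2, replace = TRUE)
  array(rpois(prod(dims), 0.8), dims)
}
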