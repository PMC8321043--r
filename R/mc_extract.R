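# Baseline (full-scan) marching cubes: classify every cell, interpolate the
# crossed edges, emit triangles, weld shared vertices.

#' Linear interpolation of the isosurface crossing along a cube edge
#'
#' Returns the point where the scalar field, assumed linear along the edge
#' from \code{p_a} (value \code{v_a}) to \code{p_b} (value \code{v_b}),
#' equals \code{iso}: \code{p_a + t (p_b - p_a)} with
#' \code{t = (iso - v_a) / (v_b - v_a)} clamped to [0, 1].
#'
#' @param p_a,p_b Numeric length-3 edge endpoints.
#' @param v_a,v_b Scalar values at the endpoints; must straddle \code{iso}
#'   (one may equal it).
#' @param iso Iso threshold.
#' @return Numeric length-3 point on the segment.
#' @export
#' @examples
#' interpolate_edge(c(0, 0, 0), c(1, 0, 0), 0, 100, 50)  # midpoint
interpolate_edge <- function(p_a, p_b, v_a, v_b, iso) {
  if (!all(is.finite(c(p_a, p_b, v_a, v_b, iso))))
    .hc_stop("interpolate_edge requires finite inputs", "data")
  if ((v_a - iso) * (v_b - iso) > 0)
    .hc_stop("edge endpoints do not straddle the iso value", "data")
  t <- (iso - v_a) / (v_b - v_a)
  t <- min(max(t, 0), 1)
  p_a + t * (p_b - p_a)
}

# derived lookup tables for vectorized emission
.hc_emit_tables <- function() {
  if (!is.null(.hc_cache$emit)) return(.hc_cache$emit)
  tt <- mc_triangle_table()
  cnt <- vapply(tt, nrow, integer(1))
  maxtri <- max(cnt)
  TE <- matrix(NA_integer_, 256, 3 * maxtri)
  for (i in seq_along(tt)) {
    tr <- tt[[i]]
    if (nrow(tr)) TE[i, seq_len(3 * nrow(tr))] <- as.vector(t(tr))
  }
  .hc_cache$emit <- list(count = cnt, TE = TE, maxtri = maxtri)
  .hc_cache$emit
}

# cube index for every cell: array over the (nx-1)(ny-1)(nz-1) cell grid
.hc_cell_index_grid <- function(volume, iso) {
  vals <- volume$values
  d <- dim(vals)
  outer_bit <- vals < iso
  co <- mc_corner_offsets()
  idx <- array(0L, d - 1L)
  for (b in 0:7) {
    o <- co[b + 1, ]
    idx <- idx + bitwShiftL(1L, b) *
      outer_bit[(1 + o[1]):(d[1] - 1 + o[1]),
                (1 + o[2]):(d[2] - 1 + o[2]),
                (1 + o[3]):(d[3] - 1 + o[3]), drop = FALSE]
  }
  storage.mode(idx) <- "integer"
  idx
}

# vectorized triangle emission for the given (cell, within-cell triangle)
# work items; cells are 1-based linear indices into the cell grid, in the
# order the triangles are to be emitted. Interpolation always runs from the
# lexicographically lower lattice endpoint of each crossed edge, so the two
# cells sharing a lattice edge produce bit-identical vertex coordinates.
.hc_emit_soup <- function(volume, iso, cell_lin, j, idx_grid) {
  d <- dim(volume$values)
  cd <- d - 1L
  m <- length(cell_lin)
  if (!m) return(mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                      weld_keys = integer(0)))
  et <- .hc_emit_tables()
  idxp <- idx_grid[cell_lin]
  e3 <- cbind(et$TE[cbind(idxp + 1L, (j - 1L) * 3L + 1L)],
              et$TE[cbind(idxp + 1L, (j - 1L) * 3L + 2L)],
              et$TE[cbind(idxp + 1L, (j - 1L) * 3L + 3L)])
  e_all <- as.vector(t(e3))                     # 3m edge ids, triangle-major
  cl0 <- rep(cell_lin - 1L, each = 3L)
  cx <- cl0 %% cd[1]
  cy <- (cl0 %/% cd[1]) %% cd[2]
  cz <- cl0 %/% (cd[1] * cd[2])
  A <- cbind(cx + .hc_edge_base[e_all, 1],
             cy + .hc_edge_base[e_all, 2],
             cz + .hc_edge_base[e_all, 3])      # lower lattice endpoint, 0-based
  axis <- .hc_edge_axis[e_all]
  step <- c(1L, d[1], d[1] * d[2])
  linA <- A[, 1] + A[, 2] * d[1] + A[, 3] * d[1] * d[2] + 1L
  linB <- linA + step[axis]
  v_a <- volume$values[linA]
  v_b <- volume$values[linB]
  t <- (iso - v_a) / (v_b - v_a)
  t <- pmin(pmax(t, 0), 1)
  P <- A * 1.0
  sel <- cbind(seq_len(3L * m), axis)
  P[sel] <- P[sel] + t
  P <- P * rep(volume$spacing, each = 3L * m)
  keys <- (linA - 1L) * 3L + axis
  mesh(P, matrix(seq_len(3L * m), ncol = 3, byrow = TRUE), weld_keys = keys)
}

#' Weld shared vertices of a triangle soup
#'
#' Triangle corners generated on the same volume lattice edge are stored
#' once. The weld key is exact integer identity of (lattice edge, axis) --
#' no floating-point tolerance -- so welding is deterministic, geometry is
#' unchanged, and the triangle count is preserved. Welding an already-welded
#' mesh is a no-op.
#'
#' @param soup A soup \code{\link{mesh}} carrying \code{weld_keys} (as
#'   produced by the extractors with \code{weld = FALSE}).
#' @return A \code{\link{mesh}} with \code{vertex count <= soup vertex count}.
#' @export
weld_vertices <- function(soup) {
  if (is.null(soup$weld_keys))
    .hc_stop("mesh carries no weld keys; only extractor output can be welded",
             "data")
  keys <- soup$weld_keys
  fu <- unique(keys)
  if (length(fu) == nrow(soup$vertices) &&
      all(keys == fu)) return(soup)            # already welded
  map <- match(keys, fu)
  verts <- soup$vertices[match(fu, keys), , drop = FALSE]
  tris <- matrix(map[soup$triangles], ncol = 3)
  mesh(verts, tris, weld_keys = fu)
}

# drop triangles whose corners coincide (repeated index after welding, or
# coincident coordinates when iso hits a lattice value exactly)
.hc_drop_degenerate <- function(m) {
  tr <- m$triangles
  if (!nrow(tr)) return(m)
  v <- m$vertices
  same <- function(i, j) {
    a <- v[tr[, i], , drop = FALSE]
    b <- v[tr[, j], , drop = FALSE]
    a[, 1] == b[, 1] & a[, 2] == b[, 2] & a[, 3] == b[, 3]
  }
  bad <- same(1, 2) | same(2, 3) | same(1, 3)
  if (any(bad)) {
    message(sprintf("dropped %d degenerate triangle(s)", sum(bad)))
    m$triangles <- tr[!bad, , drop = FALSE]
  }
  m
}

.hc_check_iso <- function(volume, iso) {
  if (!inherits(volume, "volume")) .hc_stop("not a volume object", "data")
  if (length(iso) != 1L || !is.finite(iso)) .hc_stop("iso must be a finite scalar", "data")
  if (iso <= volume$intensity_range[1] || iso > volume$intensity_range[2]) {
    warning(sprintf("iso = %g lies outside the data range [%g, %g]; the mesh is empty",
                    iso, volume$intensity_range[1], volume$intensity_range[2]))
    return(FALSE)
  }
  TRUE
}

.hc_finish_mesh <- function(soup, weld) {
  m <- if (weld) weld_vertices(soup) else soup
  m <- .hc_drop_degenerate(m)
  m$normals <- if (nrow(m$triangles)) triangle_normals(m) else NULL
  m
}

#' Full-scan marching-cubes surface extraction
#'
#' Visits all \code{(nx-1)(ny-1)(nz-1)} cells in fixed z-outer, y, x-inner
#' order, classifies each cell's corners against \code{iso} (a corner is
#' inner when its value is >= iso), and emits the case table's triangles
#' with linearly interpolated vertices. Degenerate triangles (possible only
#' when \code{iso} equals a lattice value exactly) are dropped with a
#' message.
#'
#' @param volume A \code{\link{volume}}.
#' @param iso Iso threshold in intensity units.
#' @param weld Share vertices across cells via exact lattice-edge identity
#'   (default); \code{FALSE} returns the triangle soup.
#' @return A \code{\link{mesh}} with per-triangle normals pointing from the
#'   inner (>= iso) toward the outer region. An iso value outside the data
#'   range yields a warning and an empty mesh.
#' @export
#' @examples
#' v <- sphere_volume(n = 24, r = 8)
#' m <- extract_mesh_baseline(v, 128)
#' mesh_topology(m)$watertight
extract_mesh_baseline <- function(volume, iso, weld = TRUE) {
  if (!.hc_check_iso(volume, iso))
    return(.hc_finish_mesh(.hc_emit_soup(volume, iso, integer(0), integer(0),
                                         NULL), weld))
  idx_grid <- .hc_cell_index_grid(volume, iso)
  cnt <- .hc_emit_tables()$count[idx_grid + 1L]
  active <- which(cnt > 0L)                     # ascending = (z, y, x) order
  cell_lin <- rep(active, cnt[active])
  j <- sequence(cnt[active])
  soup <- .hc_emit_soup(volume, iso, cell_lin, j, idx_grid)
  .hc_finish_mesh(soup, weld)
}
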