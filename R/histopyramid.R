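# Histogram pyramid over a 2D/3D grid of nonnegative output counts:
# each level halves every axis, each parent stores the sum of its 2^d
# children, and the single apex cell holds the total output count M. The
# k-th output item is located by descending from the apex, at each level
# scanning the current cell's children in fixed x-fastest order and entering
# the child whose half-open index range [start, start + count) contains k --
# O(log N) per lookup.

#' Build a histogram pyramid over a grid of output counts
#'
#' The base grid is zero-padded to a power-of-two square/cube; padded cells
#' carry zero at every level and can never surface in a traversal result.
#'
#' @param base_counts 2D or 3D array (or matrix) of nonnegative integers,
#'   one output count per base cell.
#' @return Object of class \code{histopyramid} with fields \code{levels}
#'   (base first, apex last), \code{base_extent} and \code{apex} (total
#'   count M).
#' @export
#' @examples
#' counts <- matrix(c(2, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 0, 0, 0),
#'                  4, 4, byrow = TRUE)  # rows = y, columns = x
#' hp <- hp_build(t(counts))             # array indexed [x, y]
#' hp$apex
hp_build <- function(base_counts) {
  if (is.matrix(base_counts)) base_counts <- array(base_counts, dim(base_counts))
  d <- dim(base_counts)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    .hc_stop("base_counts must be a 2D or 3D array", "data")
  if (any(!is.finite(base_counts)) || any(base_counts < 0) ||
      any(base_counts != round(base_counts)))
    .hc_stop("counts must be nonnegative integers", "data")
  P <- 2^ceiling(log2(max(d)))
  padded <- array(0, rep(P, length(d)))
  if (length(d) == 2L) padded[seq_len(d[1]), seq_len(d[2])] <- base_counts
  else padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- base_counts
  levels <- list(padded)
  while (dim(levels[[length(levels)]])[1] > 1L) {
    a <- levels[[length(levels)]]
    da <- dim(a)
    o <- seq(1, da[1], by = 2)
    e <- o + 1
    nxt <- if (length(da) == 2L) {
      a[o, o, drop = FALSE] + a[e, o, drop = FALSE] +
        a[o, e, drop = FALSE] + a[e, e, drop = FALSE]
    } else {
      a[o, o, o, drop = FALSE] + a[e, o, o, drop = FALSE] +
        a[o, e, o, drop = FALSE] + a[e, e, o, drop = FALSE] +
        a[o, o, e, drop = FALSE] + a[e, o, e, drop = FALSE] +
        a[o, e, e, drop = FALSE] + a[e, e, e, drop = FALSE]
    }
    levels[[length(levels) + 1L]] <- nxt
  }
  structure(list(levels = levels, base_extent = d,
                 apex = as.numeric(levels[[length(levels)]][1])),
            class = "histopyramid")
}

#' @export
print.histopyramid <- function(x, ...) {
  cat(sprintf("<histopyramid> base %s (padded %s), %d levels, apex %g\n",
              paste(x$base_extent, collapse = " x "),
              paste(dim(x$levels[[1]]), collapse = " x "),
              length(x$levels), x$apex))
  invisible(x)
}

# child offsets in fixed scan order: x fastest, then y, then z
.hc_child_offsets <- function(d) {
  if (d == 2L) cbind(x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L))
  else cbind(x = rep(c(0L, 1L), 4), y = rep(rep(c(0L, 1L), each = 2), 2),
             z = rep(c(0L, 1L), each = 4))
}

#' Resolve the k-th output item to its base cell
#'
#' Descends the pyramid from the apex: at each level the current cell's
#' children are scanned in x-fastest order, accumulating their counts into
#' half-open index ranges, and the child whose range contains \code{k} is
#' entered. The number of descent steps equals the number of levels minus
#' one, i.e. grows logarithmically in the padded extent.
#'
#' @param hp A \code{\link{hp_build}} pyramid.
#' @param k Output index, 0-based, with \code{0 <= k < apex}.
#' @return List with \code{cell} (0-based base-cell coordinates), \code{offset}
#'   (\code{k} minus the start of the cell's range), \code{steps} (descent
#'   levels) and \code{ranges} (two-column matrix of every half-open range
#'   examined on the path, apex first).
#' @export
#' @examples
#' counts <- t(matrix(c(2, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 0, 0, 0),
#'                    4, 4, byrow = TRUE))
#' hp_traverse(hp_build(counts), 4)$cell  # (2, 1)
hp_traverse <- function(hp, k) {
  if (!inherits(hp, "histopyramid")) .hc_stop("not a histopyramid", "data")
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 0 || k >= hp$apex)
    .hc_stop(sprintf("output index k = %s outside [0, %g)", format(k), hp$apex),
             "data")
  d <- length(dim(hp$levels[[1]]))
  offs <- .hc_child_offsets(d)
  nlev <- length(hp$levels)
  cell <- rep(0L, d)
  start <- 0
  ranges <- matrix(c(0, hp$apex), 1, 2,
                   dimnames = list(NULL, c("start", "end")))
  if (nlev > 1L) for (lev in (nlev - 1L):1L) {
    a <- hp$levels[[lev]]
    da <- dim(a)
    base <- 2L * cell
    for (ci in seq_len(nrow(offs))) {
      child <- base + offs[ci, ]
      cnt <- if (d == 2L) a[child[1] + 1L, child[2] + 1L]
             else a[child[1] + 1L, child[2] + 1L, child[3] + 1L]
      ranges <- rbind(ranges, c(start, start + cnt))
      if (k < start + cnt) {
        cell <- child
        break
      }
      start <- start + cnt
    }
  }
  list(cell = as.integer(cell), offset = as.integer(k - start),
       steps = nlev - 1L, ranges = ranges)
}

#' Compact a pyramid into the ordered list of output work items
#'
#' Equivalent to \code{hp_traverse(hp, k)} for every \code{k} from 0 to
#' apex - 1, computed as one batched level-by-level descent. Each row of the
#' result is (base cell, within-cell offset); the multiset of cells with
#' multiplicity reproduces the base counts exactly.
#'
#' @param hp A \code{\link{hp_build}} pyramid.
#' @return List with \code{cells} (M x d integer matrix of 0-based base-cell
#'   coordinates, one row per output index k = 0, ..., M - 1) and
#'   \code{offsets} (integer vector of within-cell output indices).
#' @export
hp_compact <- function(hp) {
  if (!inherits(hp, "histopyramid")) .hc_stop("not a histopyramid", "data")
  d <- length(dim(hp$levels[[1]]))
  M <- hp$apex
  if (M == 0)
    return(list(cells = matrix(integer(0), 0, d), offsets = integer(0)))
  offs <- .hc_child_offsets(d)
  k <- seq_len(M) - 1
  cell <- matrix(0L, M, d)
  start <- numeric(M)
  nlev <- length(hp$levels)
  if (nlev > 1L) for (lev in (nlev - 1L):1L) {
    a <- hp$levels[[lev]]
    da <- dim(a)
    placed <- rep(FALSE, M)
    base <- 2L * cell
    newcell <- cell
    for (ci in seq_len(nrow(offs))) {
      child <- base + matrix(offs[ci, ], M, d, byrow = TRUE)
      lin <- child[, 1] + da[1] * child[, 2] +
        (if (d == 3L) da[1] * da[2] * child[, 3] else 0L) + 1L
      cnt <- a[lin]
      enter <- !placed & (k < start + cnt)
      if (any(enter)) {
        newcell[enter, ] <- child[enter, , drop = FALSE]
        placed <- placed | enter
      }
      adv <- !placed
      if (any(adv)) start[adv] <- start[adv] + cnt[adv]
      if (all(placed)) break
    }
    cell <- newcell
  }
  list(cells = cell, offsets = as.integer(k - start))
}
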