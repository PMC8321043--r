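# Mesh quality metrics: density (stored vertex count) and a local-window
# curvature roughness. Mesh density is the field's usual proxy for surface
# roughness: duplicated vertices from unwelded extraction inflate density
# without adding geometry.

#' Mesh density
#'
#' The number of distinct stored vertices -- the standard density measure
#' for comparing extraction pipelines (a welded mesh is strictly denser in
#' information but smaller in storage than the raw triangle soup).
#'
#' @param mesh A \code{\link{mesh}}.
#' @return Integer vertex count.
#' @export
mesh_density <- function(mesh) {
  if (!inherits(mesh, "mesh")) .hc_stop("not a mesh object", "data")
  nrow(mesh$vertices)
}

# 1-ring structure shared by vertex_curvature / roughness:
# neighbor sums, degrees, mean incident edge length, boundary flags
.hc_one_ring <- function(mesh) {
  el <- unique(.hc_mesh_edge_list(mesh))
  n <- nrow(mesh$vertices)
  both <- rbind(el, el[, c(2, 1), drop = FALSE])
  deg <- tabulate(both[, 1], nbins = n)
  nb_sum <- rowsum(mesh$vertices[both[, 2], , drop = FALSE], both[, 1],
                   reorder = FALSE)
  nb_sum_full <- matrix(0, n, 3)
  nb_sum_full[as.integer(rownames(nb_sum)), ] <- nb_sum
  elen <- sqrt(rowSums((mesh$vertices[both[, 1], , drop = FALSE] -
                          mesh$vertices[both[, 2], , drop = FALSE])^2))
  len_sum <- rowsum(elen, both[, 1], reorder = FALSE)
  len_full <- numeric(n)
  len_full[as.integer(rownames(len_sum))] <- len_sum
  # boundary vertices: incident to an edge used by != 2 triangles
  all_e <- .hc_mesh_edge_list(mesh)
  ek <- (all_e[, 1] - 1) * n + all_e[, 2]
  mult <- table(ek)
  bad_keys <- as.numeric(names(mult)[mult != 2L])
  boundary <- rep(FALSE, n)
  if (length(bad_keys)) {
    boundary[(bad_keys - 1) %/% n + 1] <- TRUE
    boundary[(bad_keys - 1) %% n + 1] <- TRUE
  }
  list(deg = deg, nb_mean = nb_sum_full / pmax(deg, 1),
       mean_elen = len_full / pmax(deg, 1), boundary = boundary)
}

#' Umbrella-operator curvature estimate per vertex
#'
#' For each eligible vertex v the estimate is the normal-projected umbrella
#' operator over the 1-ring local window,
#' \deqn{\hat\kappa(v) = 2\,|(v - \bar{n}(v)) \cdot \hat{n}(v)| / \bar{\ell}(v)^2,}
#' where \eqn{\bar{n}(v)} is the mean of the 1-ring neighbors,
#' \eqn{\hat{n}(v)} the area-weighted vertex normal and \eqn{\bar\ell(v)}
#' the mean incident edge length. Projecting onto the normal discards the
#' tangential drift an irregular ring induces, so the estimate carries units
#' 1/length and behaves like an unsigned mean curvature: on a sphere of
#' radius r it approaches 1/r, on a plane it is 0, and scaling a mesh by a
#' factor s divides it by s (exactly, under the formula). Isolated (degree
#' < 3) and boundary vertices are excluded and reported as NA.
#'
#' @param mesh A welded \code{\link{mesh}}.
#' @param vertex Optional vertex index (1-based); default all vertices.
#' @return Numeric vector of curvature estimates (NA where excluded).
#' @export
vertex_curvature <- function(mesh, vertex = NULL) {
  if (!inherits(mesh, "mesh")) .hc_stop("not a mesh object", "data")
  if (!nrow(mesh$triangles)) .hc_stop("mesh has no triangles", "data")
  ring <- .hc_one_ring(mesh)
  disp <- mesh$vertices - ring$nb_mean
  vn <- .hc_vertex_normals(mesh)
  kappa <- 2 * abs(rowSums(disp * vn)) / ring$mean_elen^2
  kappa[ring$deg < 3L | ring$boundary] <- NA_real_
  if (!is.null(vertex)) kappa[vertex] else kappa
}

# area-weighted vertex normals (sum of incident triangle cross products)
.hc_vertex_normals <- function(mesh) {
  tr <- mesh$triangles
  v <- mesh$vertices
  a <- v[tr[, 1], , drop = FALSE]
  u <- v[tr[, 2], , drop = FALSE] - a
  w <- v[tr[, 3], , drop = FALSE] - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    s <- rowsum(fn, tr[, k], reorder = FALSE)
    rows <- as.integer(rownames(s))
    vn[rows, ] <- vn[rows, ] + s
  }
  vn / pmax(sqrt(rowSums(vn^2)), .Machine$double.xmin)
}

#' Mesh roughness: mean local curvature
#'
#' The mean of \code{\link{vertex_curvature}} over all eligible (interior,
#' degree >= 3) vertices. Requires a welded mesh: on a triangle soup every
#' vertex is a boundary vertex and the metric is undefined.
#'
#' @param mesh A welded \code{\link{mesh}}.
#' @return Scalar roughness (1/length units).
#' @export
roughness <- function(mesh) {
  k <- vertex_curvature(mesh)
  k <- k[!is.na(k)]
  if (!length(k))
    .hc_stop("no eligible interior vertex; is the mesh welded?", "data")
  mean(k)
}

#' Assemble a metrics report for an extraction
#'
#' Bundles the quantities used to compare extraction pipelines: welded and
#' soup vertex counts, triangle count, roughness, and per-stage timings.
#' Timings are reported for information only; they are hardware-dependent
#' and never asserted against.
#'
#' @param mesh The welded \code{\link{mesh}}.
#' @param soup_vertex_count Vertex count before welding (3 x triangle count
#'   straight out of the extractor).
#' @param timings Named list of per-stage wall-clock seconds.
#' @return Object of class \code{metrics_report} (a named list with fields
#'   \code{vertex_count}, \code{triangle_count}, \code{soup_vertex_count},
#'   \code{roughness}, \code{timings}).
#' @export
metrics_report <- function(mesh, soup_vertex_count = NA_integer_,
                           timings = list()) {
  r <- if (nrow(mesh$triangles)) tryCatch(roughness(mesh),
                                          error = function(e) NA_real_)
       else NA_real_
  structure(list(vertex_count = mesh_density(mesh),
                 triangle_count = nrow(mesh$triangles),
                 soup_vertex_count = as.integer(soup_vertex_count),
                 roughness = r,
                 timings = timings),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics> vertices %d (soup %s), triangles %d, roughness %s\n",
              x$vertex_count,
              ifelse(is.na(x$soup_vertex_count), "?", x$soup_vertex_count),
              x$triangle_count,
              ifelse(is.na(x$roughness), "NA", format(x$roughness, digits = 4))))
  if (length(x$timings))
    cat("  timings (s):", paste(sprintf("%s=%.3f", names(x$timings),
                                        unlist(x$timings)), collapse = " "), "\n")
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A \code{\link{metrics_report}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
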