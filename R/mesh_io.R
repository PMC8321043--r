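# Mesh readers/writers: Wavefront OBJ (ASCII), PLY (ASCII or binary
# little-endian), STL (binary). Indices are 1-based in memory; OBJ's 1-based
# and PLY/STL's 0-based conventions are handled at the format boundary.

.hc_mesh_format <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (!format %in% c("obj", "ply", "stl"))
    .hc_stop(sprintf("unsupported mesh format '%s' (use obj, ply or stl)",
                     format), "usage")
  format
}

#' Write a mesh to OBJ, PLY or STL
#'
#' OBJ and ASCII PLY are plain text; \code{binary = TRUE} selects binary
#' little-endian PLY. STL is always the binary flavor (80-byte header,
#' uint32 facet count); note STL stores independent facets, so vertex
#' connectivity is not preserved through an STL round-trip.
#'
#' @param mesh A \code{\link{mesh}}.
#' @param path Output file path; the extension picks the format unless
#'   \code{format} is given.
#' @param format One of \code{"obj"}, \code{"ply"}, \code{"stl"}.
#' @param binary For PLY only: write binary little-endian instead of ASCII.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- .hc_mesh_format(path, format)
  ok <- switch(format,
    obj = .hc_write_obj(mesh, path),
    ply = .hc_write_ply(mesh, path, binary),
    stl = .hc_write_stl(mesh, path))
  invisible(path)
}

#' Read a mesh from OBJ, PLY or STL
#'
#' @param path Input file; extension picks the format unless given.
#' @param format One of \code{"obj"}, \code{"ply"}, \code{"stl"}.
#' @return A \code{\link{mesh}} (STL yields a triangle soup: three vertices
#'   per facet).
#' @export
read_mesh <- function(path, format = NULL) {
  format <- .hc_mesh_format(path, format)
  if (!file.exists(path))
    .hc_stop(sprintf("mesh file not found: %s", path), "io")
  switch(format,
    obj = .hc_read_obj(path),
    ply = .hc_read_ply(path),
    stl = .hc_read_stl(path))
}

.hc_open_w <- function(path, bin = FALSE) {
  con <- tryCatch(file(path, if (bin) "wb" else "w"),
                  error = function(e) .hc_stop(
                    sprintf("cannot open %s for writing: %s",
                            path, conditionMessage(e)), "io"))
  con
}

.hc_write_obj <- function(mesh, path) {
  con <- .hc_open_w(path)
  on.exit(close(con))
  writeLines("# histocubes OBJ export", con)
  if (nrow(mesh$vertices))
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$triangles))
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con)
  TRUE
}

.hc_read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v([[:space:]])", lines, value = TRUE)
  fl <- grep("^f([[:space:]])", lines, value = TRUE)
  parse3 <- function(s, what, lead) {
    parts <- strsplit(trimws(sub(lead, "", s)), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) < 3L)
    if (length(bad))
      .hc_stop(sprintf("malformed OBJ record '%s' in %s", s[bad[1]], path), "io")
    t(vapply(parts, function(p) what(p[1:3]), what(c("0", "0", "0"))))
  }
  verts <- if (length(vl))
    parse3(vl, function(p) as.numeric(p), "^v") else matrix(numeric(0), 0, 3)
  tris <- if (length(fl)) {
    # face entries may be v, v/vt, v/vt/vn or v//vn; keep the vertex index
    m <- parse3(fl, function(p) as.integer(sub("/.*$", "", p)), "^f")
    m
  } else matrix(integer(0), 0, 3)
  if (any(!is.finite(verts)) || (nrow(tris) && any(is.na(tris))))
    .hc_stop(sprintf("malformed OBJ numeric data in %s", path), "io")
  if (nrow(tris) && min(tris) < 0)  # negative = relative indexing
    tris[tris < 0] <- nrow(verts) + 1L + tris[tris < 0]
  mesh(verts, tris)
}

.hc_write_ply <- function(mesh, path, binary) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              "comment histocubes PLY export",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- .hc_open_w(path, bin = TRUE)
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    if (nv) writeBin(as.vector(t(mesh$vertices)), con, size = 8,
                     endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- .hc_open_w(path)
    on.exit(close(con))
    writeLines(header, con)
    if (nv) writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                               mesh$vertices[, 2], mesh$vertices[, 3]), con)
    if (nf) writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                               mesh$triangles[, 2] - 1L,
                               mesh$triangles[, 3] - 1L), con)
  }
  TRUE
}

.hc_read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  l1 <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(trimws(l1), "ply"))
    .hc_stop(sprintf("%s is not a PLY file (bad magic line)", path), "io")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) .hc_stop(sprintf("PLY header truncated in %s", path), "io")
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (!length(toks)) next
    if (toks[1] == "comment") next
    if (toks[1] == "format") fmt <- toks[2]
    else if (toks[1] == "element") {
      cur <- toks[2]
      elements[[cur]] <- list(count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property") {
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1L]] <- toks[-1]
    } else if (toks[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    .hc_stop(sprintf("unsupported PLY format '%s' in %s", fmt, path), "io")
  if (is.null(elements$vertex) || is.null(elements$face))
    .hc_stop(sprintf("PLY without vertex/face elements: %s", path), "io")
  nv <- elements$vertex$count
  nf <- elements$face$count
  vprops <- elements$vertex$props
  pnames <- vapply(vprops, function(p) p[length(p)], character(1))
  xyz <- match(c("x", "y", "z"), pnames)
  if (anyNA(xyz)) .hc_stop(sprintf("PLY vertex element lacks x/y/z: %s", path), "io")
  sz <- function(t) switch(t, "char" = , "uchar" = , "int8" = , "uint8" = 1L,
                           "short" = , "ushort" = , "int16" = , "uint16" = 2L,
                           "int" = , "uint" = , "int32" = , "uint32" = ,
                           "float" = , "float32" = 4L,
                           "double" = , "float64" = 8L,
                           .hc_stop(sprintf("PLY type '%s' unsupported", t), "io"))
  rd <- function(cn, t, n = 1L) {
    what <- if (t %in% c("float", "float32", "double", "float64"))
      "numeric" else "integer"
    v <- readBin(cn, what, n = n, size = sz(t),
                 signed = !(t %in% c("uchar", "uint8", "ushort", "uint16")),
                 endian = "little")
    if (length(v) < n) .hc_stop(sprintf("PLY data truncated in %s", path), "io")
    v
  }
  verts <- matrix(0, nv, 3)
  tris <- matrix(0L, nf, 3)
  if (fmt == "ascii") {
    need_tokens <- function(n_line) {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (!length(line))
        .hc_stop(sprintf("PLY data truncated at line %d of %s", n_line, path), "io")
      strsplit(trimws(line), "[[:space:]]+")[[1]]
    }
    for (i in seq_len(nv)) {
      toks <- as.numeric(need_tokens(i))
      if (length(toks) < length(vprops) || any(!is.finite(toks[xyz])))
        .hc_stop(sprintf("malformed PLY vertex %d in %s", i, path), "io")
      verts[i, ] <- toks[xyz]
    }
    for (i in seq_len(nf)) {
      toks <- as.integer(need_tokens(nv + i))
      if (length(toks) < 1L || toks[1] != 3L || length(toks) < 4L)
        .hc_stop(sprintf("PLY face %d is not a triangle in %s", i, path), "io")
      tris[i, ] <- toks[2:4] + 1L
    }
  } else {
    for (i in seq_len(nv)) {
      row <- numeric(length(vprops))
      for (j in seq_along(vprops)) row[j] <- rd(con, vprops[[j]][1])
      verts[i, ] <- row[xyz]
    }
    fp <- elements$face$props[[1]]  # list <count type> <index type> <name>
    if (fp[1] != "list") .hc_stop(sprintf("PLY face property is not a list: %s",
                                          path), "io")
    for (i in seq_len(nf)) {
      cnt <- rd(con, fp[2])
      if (cnt != 3L)
        .hc_stop(sprintf("PLY face %d is not a triangle in %s", i, path), "io")
      tris[i, ] <- rd(con, fp[3], 3L) + 1L
    }
  }
  mesh(verts, tris)
}

.hc_write_stl <- function(mesh, path) {
  con <- .hc_open_w(path, bin = TRUE)
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "histocubes binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$triangles)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  nrm <- if (nf) tryCatch(triangle_normals(mesh),
                          error = function(e) matrix(0, nf, 3))
  for (i in seq_len(nf)) {
    writeBin(as.numeric(nrm[i, ]), con, size = 4, endian = "little")
    for (k in 1:3)
      writeBin(as.numeric(mesh$vertices[mesh$triangles[i, k], ]), con,
               size = 4, endian = "little")
    writeBin(as.integer(0L), con, size = 2, endian = "little")
  }
  TRUE
}

.hc_read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 84)
    .hc_stop(sprintf("STL file too short (%s bytes): %s", sz, path), "io")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4, endian = "little")
  if (sz < 84 + 50 * nf)
    .hc_stop(sprintf("truncated STL: header promises %d facets but %d bytes remain in %s",
                     nf, sz - 84, path), "io")
  verts <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4, endian = "little")
    readBin(con, "integer", n = 1L, size = 2, signed = FALSE)
    verts[(i - 1) * 3 + (1:3), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  mesh(verts, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}
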