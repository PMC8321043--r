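# Volume container and readers for slice stacks and raw scalar volumes.

#' Construct a scalar volume
#'
#' A volume is a 3D scalar field sampled on a regular lattice: an
#' \code{nx x ny x nz} array of intensities (x = image column, y = image row,
#' z = slice; voxel centers at 0-based integer coordinates) plus a physical
#' voxel spacing per axis. Surface extraction needs at least two samples per
#' axis, so a cube can pair slice k with slice k + 1.
#'
#' @param values Numeric 3D array, dimensions (nx, ny, nz).
#' @param spacing Numeric length-3 physical voxel size per axis; default 1.
#' @return Object of class \code{volume} with fields \code{values},
#'   \code{spacing} and \code{intensity_range}.
#' @export
#' @examples
#' v <- volume(array(0, c(4, 4, 4)))
#' dim(v$values)
volume <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    .hc_stop("values must be a 3D array", "data")
  if (any(dim(values) < 2L))
    .hc_stop("volume needs extent >= 2 along every axis", "data")
  if (!all(is.finite(values)))
    .hc_stop("volume values must all be finite", "data")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    .hc_stop("spacing must be 3 positive finite numbers", "data")
  structure(list(values = values, spacing = as.numeric(spacing),
                 intensity_range = range(values)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume> %d x %d x %d, spacing (%s), intensities [%g, %g]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = ", "),
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

# one 2D slice (matrix [x, y], intensities 0-255) from one image file
.hc_read_slice <- function(path) {
  if (!file.exists(path))
    .hc_stop(sprintf("slice file not found: %s", path), "io")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      warning(sprintf("multi-channel image %s converted by channel mean",
                      basename(path)))
      img <- apply(img, c(1, 2), mean)
    }
    # readPNG scales 8-bit samples to v/255; exact for 8-bit gray input
    return(t(img * 255))
  }
  if (ext %in% c("pgm", "ppm")) return(.hc_read_pnm(path))
  .hc_stop(sprintf("unsupported slice format '%s' (%s); use PNG or PGM",
                   ext, basename(path)), "usage")
}

# minimal PGM/PPM reader (P2/P5/P3/P6, maxval <= 255)
.hc_read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok_buf <- character(0)
  next_token <- function() {
    while (!length(tok_buf)) {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (!length(line)) .hc_stop(sprintf("truncated PNM header: %s", path), "io")
      line <- sub("#.*$", "", line)
      tok_buf <<- strsplit(trimws(line), "[[:space:]]+")[[1]]
      tok_buf <<- tok_buf[nzchar(tok_buf)]
    }
    t1 <- tok_buf[1]
    tok_buf <<- tok_buf[-1]
    t1
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5", "P3", "P6"))
    .hc_stop(sprintf("not a supported PNM file (%s): %s", magic, path), "io")
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255L)
    .hc_stop(sprintf("unsupported PNM header in %s", path), "io")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    v <- integer(0)
    while (length(v) < n) {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (!length(line)) break
      v <- c(v, as.integer(strsplit(trimws(sub("#.*$", "", line)),
                                    "[[:space:]]+")[[1]]))
    }
    v
  }
  if (length(vals) < n)
    .hc_stop(sprintf("truncated PNM pixel data: %s", path), "io")
  vals <- vals[seq_len(n)]
  if (nch == 3L) {
    warning(sprintf("multi-channel image %s converted by channel mean",
                    basename(path)))
    vals <- colMeans(matrix(vals, nrow = 3L))
  }
  matrix(vals, nrow = w, ncol = h)  # stored row-major: x fastest
}

#' Read a stack of grayscale slices into a volume
#'
#' Slices are read in the order given; slice i occupies plane z = i - 1.
#' All slices must share one width and height. 8-bit grayscale PNG and PGM
#' are supported; multi-channel images are converted by unweighted channel
#' mean with a warning.
#'
#' @param paths Character vector of at least two image files, in z order
#'   (sort them lexicographically for the usual zero-padded naming scheme).
#' @param spacing Physical voxel size per axis, default 1.
#' @return A \code{\link{volume}}; intensities in 0-255 for 8-bit input.
#' @export
#' @seealso \code{\link{write_slice_stack}} for the inverse operation.
read_slice_stack <- function(paths, spacing = c(1, 1, 1)) {
  if (length(paths) < 2L)
    .hc_stop("a slice stack needs at least 2 slices", "data")
  slices <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    s <- .hc_read_slice(paths[i])
    if (i > 1L && !identical(dim(s), dim(slices[[1]])))
      .hc_stop(sprintf(
        "slice %s is %d x %d but the stack started as %d x %d",
        basename(paths[i]), dim(s)[1], dim(s)[2],
        dim(slices[[1]])[1], dim(slices[[1]])[2]), "data")
    slices[[i]] <- s
  }
  vals <- array(unlist(slices, use.names = FALSE),
                dim = c(dim(slices[[1]]), length(slices)))
  volume(vals, spacing)
}

#' Sample-lattice size used by the per-slice storage scheme
#'
#' For a square field of view of \code{fov} pixels per side, returns
#' \code{(fov + 1)^2}, the number of dual-lattice sample points allocated per
#' slice plane by the storage arithmetic this package mirrors (e.g. a 320 x
#' 320 image yields 321 x 321 = 103,041 samples). Note the extraction
#' pipeline itself marches over \code{(nx - 1)(ny - 1)(nz - 1)} cells; both
#' conventions are deliberately exposed.
#'
#' @param fov Field of view in pixels per side, at least 1.
#' @return Integer count \code{(fov + 1)^2}.
#' @export
#' @examples
#' lattice_point_count(320)  # 103041
lattice_point_count <- function(fov) {
  if (length(fov) != 1L || !is.finite(fov) || fov < 1 || fov != round(fov))
    .hc_stop("fov must be a single integer >= 1", "data")
  (as.numeric(fov) + 1)^2
}

#' Read a raw scalar volume with an NRRD or MHD sidecar header
#'
#' Minimal readers for the two common "text header + raw block" volume
#' conventions: NRRD (header and data in one file) and MetaImage MHD (header
#' file naming a separate .raw file). Supported element types: 8-bit
#' unsigned, 16-bit unsigned/signed, 32/64-bit float; raw (uncompressed) or,
#' for NRRD, text encoding.
#'
#' @param path Path to a .nrrd or .mhd file.
#' @return A \code{\link{volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) .hc_stop(sprintf("volume file not found: %s", path), "io")
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") return(.hc_read_nrrd(path))
  if (ext == "mhd") return(.hc_read_mhd(path))
  .hc_stop(sprintf("unsupported volume format '%s'; use .nrrd or .mhd", ext),
           "usage")
}

.hc_type_spec <- function(type) {
  switch(type,
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" = , "MET_UCHAR" =
      list(what = "integer", size = 1L, signed = FALSE),
    "ushort" = , "unsigned short" = , "uint16" = , "MET_USHORT" =
      list(what = "integer", size = 2L, signed = FALSE),
    "short" = , "int16" = , "MET_SHORT" =
      list(what = "integer", size = 2L, signed = TRUE),
    "float" = , "MET_FLOAT" = list(what = "numeric", size = 4L, signed = TRUE),
    "double" = , "MET_DOUBLE" = list(what = "numeric", size = 8L, signed = TRUE),
    .hc_stop(sprintf("unsupported element type '%s'", type), "io"))
}

.hc_read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD", magic)) .hc_stop(sprintf("%s is not NRRD", path), "io")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line) || !nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) .hc_stop(sprintf("NRRD missing field '%s'", k), "io")
    fields[[k]]
  }
  dims <- as.integer(strsplit(need("sizes"), "[[:space:]]+")[[1]])
  if (as.integer(need("dimension")) != 3L || length(dims) != 3L)
    .hc_stop("only 3-dimensional NRRD volumes are supported", "io")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])
  enc <- tolower(need("encoding"))
  spec <- .hc_type_spec(tolower(need("type")))
  n <- prod(dims)
  vals <- if (enc == "raw") {
    endian <- if (!is.null(fields[["endian"]]) &&
                  tolower(fields[["endian"]]) == "big") "big" else "little"
    v <- readBin(con, spec$what, n = n, size = spec$size,
                 signed = if (spec$size <= 2) spec$signed else TRUE,
                 endian = endian)
    if (length(v) < n) .hc_stop(sprintf("truncated NRRD data in %s", path), "io")
    v
  } else if (enc %in% c("text", "txt", "ascii")) {
    v <- scan(con, what = numeric(), n = n, quiet = TRUE)
    if (length(v) < n) .hc_stop(sprintf("truncated NRRD data in %s", path), "io")
    v
  } else .hc_stop(sprintf("unsupported NRRD encoding '%s'", enc), "io")
  volume(array(vals, dim = dims), spacing)
}

.hc_read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (line in lines) {
    m <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1]]
    if (length(m) == 3L) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  need <- function(k) {
    if (is.null(kv[[k]])) .hc_stop(sprintf("MHD missing key '%s'", k), "io")
    kv[[k]]
  }
  dims <- as.integer(strsplit(need("DimSize"), "[[:space:]]+")[[1]])
  if (length(dims) != 3L)
    .hc_stop("only 3-dimensional MHD volumes are supported", "io")
  spacing <- if (!is.null(kv[["ElementSpacing"]]))
    as.numeric(strsplit(kv[["ElementSpacing"]], "[[:space:]]+")[[1]])
  else c(1, 1, 1)
  spec <- .hc_type_spec(need("ElementType"))
  raw_path <- file.path(dirname(path), need("ElementDataFile"))
  if (!file.exists(raw_path))
    .hc_stop(sprintf("MHD data file not found: %s", raw_path), "io")
  endian <- if (!is.null(kv[["BinaryDataByteOrderMSB"]]) &&
                tolower(kv[["BinaryDataByteOrderMSB"]]) == "true") "big" else "little"
  n <- prod(dims)
  v <- readBin(raw_path, spec$what, n = n, size = spec$size,
               signed = if (spec$size <= 2) spec$signed else TRUE,
               endian = endian)
  if (length(v) < n) .hc_stop(sprintf("truncated MHD data in %s", raw_path), "io")
  volume(array(v, dim = dims), spacing)
}
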