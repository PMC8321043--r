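# Deterministic synthetic volumes with known analytic geometry, standing in
# for segmented CT/MRI slice stacks so the whole pipeline is testable
# without external data. Hard-edged (binary) phantoms mimic segmented masks;
# the ramped variants add a 1-voxel linear transition at the boundary so
# edge interpolation lands on the analytic surface.

.hc_grid3 <- function(n) {
  g <- 0:(n - 1)
  list(x = array(rep(g, times = n * n), c(n, n, n)),
       y = array(rep(rep(g, each = n), times = n), c(n, n, n)),
       z = array(rep(g, each = n * n), c(n, n, n)))
}

.hc_level_to_intensity <- function(signed_dist, inside, outside, ramp) {
  # signed_dist <= 0 inside
  if (!ramp) return(ifelse(signed_dist <= 0, inside, outside))
  t <- pmin(pmax(signed_dist + 0.5, 0), 1)          # linear over +-0.5 voxel
  round(inside + (outside - inside) * t)
}

#' Sphere phantom volume
#'
#' Binary ball of radius \code{r}: voxels within distance \code{r} of the
#' center get \code{inside}, the rest \code{outside}. With \code{ramp =
#' TRUE} a 1-voxel linear intensity ramp straddles the boundary, so linear
#' edge interpolation reconstructs the analytic sphere closely.
#'
#' @param n Cubic extent (voxels per axis), at least 8.
#' @param r Radius in voxels, \code{0 < r < n/2}.
#' @param center Numeric length-3 center, default the volume midpoint
#'   \code{(n-1)/2} on each axis.
#' @param inside,outside Intensities (0-255), defaults 255 and 0.
#' @param ramp Add the 1-voxel boundary ramp (default FALSE: hard binary).
#' @return A \code{\link{volume}}.
#' @export
#' @examples
#' v <- sphere_volume(16, r = 4)
#' v$values[9, 9, 9]  # 255 at the center
sphere_volume <- function(n, r, center = rep((n - 1) / 2, 3),
                          inside = 255, outside = 0, ramp = FALSE) {
  if (n < 8) .hc_stop("sphere phantom needs n >= 8", "data")
  if (!is.finite(r) || r <= 0 || r >= n / 2)
    .hc_stop("need 0 < r < n/2", "data")
  g <- .hc_grid3(n)
  d <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  volume(.hc_level_to_intensity(d - r, inside, outside, ramp))
}

#' Torus phantom volume
#'
#' Solid torus around the z axis through the volume center: ring radius
#' \code{R}, tube radius \code{r_tube}. The extracted surface is the
#' standard genus-1 test case (Euler characteristic 0).
#'
#' @param n Cubic extent, at least 8.
#' @param R Ring (center-line) radius in voxels.
#' @param r_tube Tube radius in voxels; \code{R + r_tube < n/2}.
#' @param center Numeric length-3 center, default the volume midpoint.
#' @param inside,outside Intensities, defaults 255 and 0.
#' @param ramp Add the 1-voxel boundary ramp.
#' @return A \code{\link{volume}}.
#' @export
torus_volume <- function(n, R, r_tube, center = rep((n - 1) / 2, 3),
                         inside = 255, outside = 0, ramp = FALSE) {
  if (n < 8) .hc_stop("torus phantom needs n >= 8", "data")
  if (!is.finite(R) || !is.finite(r_tube) || R <= 0 || r_tube < 0 ||
      R + r_tube >= n / 2)
    .hc_stop("need R > 0, r_tube >= 0 and R + r_tube < n/2", "data")
  g <- .hc_grid3(n)
  rho <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  d <- sqrt((rho - R)^2 + (g$z - center[3])^2)
  volume(.hc_level_to_intensity(d - r_tube, inside, outside, ramp))
}

#' Add seeded Gaussian voxel noise to a volume
#'
#' Adds \code{N(0, noise_sd)} noise independently per voxel, rounds to
#' integer intensities and clamps to [0, 255]. The same seed always yields
#' the identical volume; the caller's RNG state is left untouched.
#'
#' @param base A \code{\link{volume}}.
#' @param noise_sd Noise standard deviation in intensity units, >= 0.
#' @param seed Integer seed.
#' @return A \code{\link{volume}}.
#' @export
noisy_volume <- function(base, noise_sd, seed = 1L) {
  if (!inherits(base, "volume")) .hc_stop("not a volume object", "data")
  if (!is.finite(noise_sd) || noise_sd < 0)
    .hc_stop("noise_sd must be >= 0", "data")
  if (noise_sd == 0) return(base)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- base$values + rnorm(length(base$values), sd = noise_sd)
  volume(array(pmin(pmax(round(v), 0), 255), dim(base$values)), base$spacing)
}

#' Write a volume to disk as a zero-padded PNG slice stack
#'
#' One 8-bit grayscale PNG per z plane, named \code{slice_0000.png},
#' \code{slice_0001.png}, ... so that lexicographic filename order is z
#' order. \code{\link{read_slice_stack}} on the output reproduces the volume
#' exactly (integer intensities 0-255 required).
#'
#' @param volume A \code{\link{volume}} with integer values in [0, 255].
#' @param dir Output directory (created if missing).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_slice_stack <- function(volume, dir) {
  if (!inherits(volume, "volume")) .hc_stop("not a volume object", "data")
  vals <- volume$values
  if (min(vals) < 0 || max(vals) > 255 || any(vals != round(vals)))
    .hc_stop("slice export needs integer intensities in [0, 255]", "data")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    .hc_stop(sprintf("cannot create directory %s", dir), "io")
  d <- dim(vals)
  paths <- file.path(dir, sprintf("slice_%04d.png", seq_len(d[3]) - 1L))
  for (z in seq_len(d[3])) {
    ok <- tryCatch({
      png::writePNG(t(vals[, , z]) / 255, paths[z])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .hc_stop(sprintf("cannot write %s", paths[z]), "io")
  }
  invisible(paths)
}
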