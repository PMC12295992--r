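# HU windowing and coordinate transforms between world mm, continuous
# voxel coordinates, and the normalized [0,1] frame the centerline
# decoder works in.

#' Intensity windowing specification
#'
#' CT windowing parameters: intensities are clipped to
#' \code{[level - width/2, level + width/2]} and mapped linearly to
#' [0, 1]. The defaults (level -200 HU, width 1400 HU) cover the CTA
#' lumen contrast range used throughout the package.
#'
#' @param level_hu window center in HU.
#' @param width_hu window width in HU, > 0.
#' @return A list of class \code{"WindowSpec"}.
#' @export
windowSpec <- function(level_hu = -200, width_hu = 1400) {
  stopifnot(is.finite(level_hu), is.finite(width_hu), width_hu > 0)
  structure(list(level_hu = level_hu, width_hu = width_hu),
            class = "WindowSpec")
}

#' Window and normalize a volume to [0, 1]
#'
#' Applies \code{clip((hu - (level - width/2)) / width, 0, 1)}. The map
#' is monotone in HU; values at the lower window edge map to 0, at the
#' center to 0.5, and at the upper edge to 1.
#'
#' @param vol an \linkS4class{ImageVolume} in HU.
#' @param w a \code{\link{windowSpec}}.
#' @return An \linkS4class{ImageVolume} with values in [0, 1].
#' @examples
#' v <- ImageVolume(array(c(-900, -200, 500), dim = c(3, 1, 1)))
#' volValues(applyWindow(v, windowSpec()))  # 0, 0.5, 1
#' @export
applyWindow <- function(vol, w = windowSpec()) {
  stopifnot(is(vol, "ImageVolume"), inherits(w, "WindowSpec"))
  lo <- w$level_hu - w$width_hu / 2
  out <- pmin(pmax((vol@values - lo) / w$width_hu, 0), 1)
  ImageVolume(out, spacing = vol@spacing, origin = vol@origin)
}

#' World mm to continuous voxel coordinates
#'
#' Voxel center \code{i} (0-based) sits at world
#' \code{origin + (i + 0.5) * spacing}. Points outside the grid are
#' returned unchanged with the \code{"outOfBounds"} attribute flagging
#' them.
#'
#' @param points N x 3 matrix of world-mm coordinates.
#' @param x an ImageVolume or ProbabilityMask defining the grid.
#' @return N x 3 matrix of continuous 0-based voxel coordinates with a
#'   logical \code{"outOfBounds"} attribute.
#' @export
worldToVoxel <- function(points, x) {
  points <- rbind(points)
  v <- sweep(sweep(points, 2, originMm(x)), 2, spacingMm(x), `/`) - 0.5
  d <- gridDim(x)
  oob <- v[, 1] < -0.5 | v[, 1] > d[1] - 0.5 |
         v[, 2] < -0.5 | v[, 2] > d[2] - 0.5 |
         v[, 3] < -0.5 | v[, 3] > d[3] - 0.5
  attr(v, "outOfBounds") <- oob
  v
}

#' Continuous voxel coordinates to world mm
#'
#' Inverse of \code{\link{worldToVoxel}}.
#'
#' @param vox N x 3 matrix of continuous 0-based voxel coordinates.
#' @param x an ImageVolume or ProbabilityMask defining the grid.
#' @return N x 3 matrix of world-mm coordinates.
#' @export
voxelToWorld <- function(vox, x) {
  vox <- rbind(vox)
  sweep(sweep(vox + 0.5, 2, spacingMm(x), `*`), 2, originMm(x), `+`)
}

#' World mm to the normalized [0,1] network frame
#'
#' The network-internal coordinate divides the continuous voxel
#' coordinate (plus half a voxel) by the grid extent per axis, so the
#' grid interior maps to [0, 1]^3.
#'
#' @param points N x 3 world-mm matrix.
#' @param x grid-defining object.
#' @return N x 3 matrix of normalized coordinates.
#' @export
worldToNormalized <- function(points, x) {
  v <- worldToVoxel(points, x)
  attr(v, "outOfBounds") <- NULL
  sweep(v + 0.5, 2, gridDim(x), `/`)
}

#' Normalized [0,1] network coordinates to world mm
#'
#' @param u N x 3 matrix of normalized coordinates.
#' @param x grid-defining object.
#' @return N x 3 matrix of world-mm coordinates.
#' @export
normalizedToWorld <- function(u, x) {
  u <- rbind(u)
  v <- sweep(u, 2, gridDim(x), `*`) - 0.5
  voxelToWorld(v, x)
}
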