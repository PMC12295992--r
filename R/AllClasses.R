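#' ImageVolume: a 3D scalar field with voxel spacing
#'
#' Container for a 3D CT/CTA volume in Hounsfield units (or normalized
#' intensities) on an axis-aligned grid. The world position of voxel
#' center \code{(i, j, k)} (0-based) is \code{origin + (index + 0.5) *
#' spacing} per axis, in millimetres.
#'
#' @slot values 3D numeric array (H x W x D).
#' @slot spacing numeric(3), voxel spacing in mm, all > 0.
#' @slot origin numeric(3), world position of the grid corner in mm.
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(2, 2, 2), origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive reals")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite reals")
    if (is.null(msg)) TRUE else msg
  })

#' ProbabilityMask: per-voxel vessel probability or binary ground truth
#'
#' Single-class voxel mask on the same grid as its ImageVolume. Values
#' lie in [0, 1]; ground-truth masks are binary (0/1).
#'
#' @slot values 3D numeric array in [0, 1].
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) world origin in mm.
#' @export
setClass("ProbabilityMask",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(2, 2, 2), origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (any(!is.finite(object@values)) ||
        any(object@values < 0) || any(object@values > 1))
      msg <- c(msg, "values must lie in [0, 1]")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive reals")
    if (is.null(msg)) TRUE else msg
  })

#' Centerline: an ordered 3D polyline in world millimetres
#'
#' Ordered point list with implicit chain connectivity (point i is
#' connected to point i+1). Coordinates are real-valued world mm.
#'
#' @slot points N x 3 numeric matrix, N >= 2, no NaN, no two consecutive
#'   points identical.
#' @export
setClass("Centerline",
  representation(points = "matrix"),
  validity = function(object) {
    p <- object@points
    msg <- NULL
    if (!is.numeric(p) || ncol(p) != 3L)
      msg <- c(msg, "points must be an N x 3 numeric matrix")
    else {
      if (nrow(p) < 2L) msg <- c(msg, "a centerline needs at least 2 points")
      if (any(!is.finite(p))) msg <- c(msg, "points must be finite")
      else if (nrow(p) >= 2L) {
        gaps <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                              p[-nrow(p), , drop = FALSE])^2))
        if (any(gaps == 0))
          msg <- c(msg, "consecutive points must not coincide")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

# ---- constructors -----------------------------------------------------

#' Create an ImageVolume
#'
#' @param values 3D numeric array of intensities (HU).
#' @param spacing voxel spacing in mm (length 3, recycled from length 1).
#' @param origin world origin in mm.
#' @return An \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a ProbabilityMask
#'
#' @param values 3D numeric array in [0, 1].
#' @param spacing voxel spacing in mm.
#' @param origin world origin in mm.
#' @return A \linkS4class{ProbabilityMask}.
#' @export
ProbabilityMask <- function(values, spacing = c(2, 2, 2),
                            origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(values) <- "double"
  new("ProbabilityMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a Centerline
#'
#' @param points N x 3 matrix of ordered world-mm coordinates.
#' @return A \linkS4class{Centerline}.
#' @export
Centerline <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  new("Centerline", points = points)
}

# ---- generics and accessors ------------------------------------------

#' Voxel values of a volume or mask
#' @param x an ImageVolume or ProbabilityMask.
#' @return The 3D numeric array.
#' @export
setGeneric("volValues", function(x) standardGeneric("volValues"))
#' @rdname volValues
#' @export
setMethod("volValues", "ImageVolume", function(x) x@values)
#' @rdname volValues
#' @export
setMethod("volValues", "ProbabilityMask", function(x) x@values)

#' Voxel spacing in mm
#' @param x an ImageVolume or ProbabilityMask.
#' @return numeric(3) spacing.
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "ImageVolume", function(x) x@spacing)
#' @rdname spacingMm
#' @export
setMethod("spacingMm", "ProbabilityMask", function(x) x@spacing)

#' World origin in mm
#' @param x an ImageVolume or ProbabilityMask.
#' @return numeric(3) origin.
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))
#' @rdname originMm
#' @export
setMethod("originMm", "ImageVolume", function(x) x@origin)
#' @rdname originMm
#' @export
setMethod("originMm", "ProbabilityMask", function(x) x@origin)

#' Grid dimensions
#' @param x an ImageVolume or ProbabilityMask.
#' @return integer(3) grid shape.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname gridDim
#' @export
setMethod("gridDim", "ImageVolume", function(x) dim(x@values))
#' @rdname gridDim
#' @export
setMethod("gridDim", "ProbabilityMask", function(x) dim(x@values))

#' Ordered points of a centerline
#' @param x a Centerline.
#' @return N x 3 matrix of world-mm coordinates.
#' @export
setGeneric("clPoints", function(x) standardGeneric("clPoints"))
#' @rdname clPoints
#' @export
setMethod("clPoints", "Centerline", function(x) x@points)

#' Number of centerline points
#' @param x a Centerline.
#' @return integer count.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname nPoints
#' @export
setMethod("nPoints", "Centerline", function(x) nrow(x@points))

#' Total polyline length in mm
#' @param x a Centerline.
#' @return numeric scalar, sum of consecutive-edge lengths.
#' @export
setGeneric("polylineLength", function(x) standardGeneric("polylineLength"))
#' @rdname polylineLength
#' @export
setMethod("polylineLength", "Centerline", function(x) {
  p <- x@points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume %d x %d x %d, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "ProbabilityMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityMask %d x %d x %d, foreground fraction %.4f\n",
              d[1], d[2], d[3], mean(object@values > 0.5)))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline with %d points, length %.1f mm\n",
              nrow(object@points), polylineLength(object)))
})
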