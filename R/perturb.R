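# Input perturbations: CT artifact models (additive Gaussian noise,
# global calibration shift, linear motion blur), rigid/deformable
# robustness transforms, and the training-time augmentation pipeline.
# Geometric perturbations transform image, mask and centerline with the
# same map; intensity perturbations never move the ground truth.

#' CT artifact specification
#'
#' Defaults follow common acquisition-artifact magnitudes: additive
#' Gaussian noise with variance 15 HU^2, a global calibration shift
#' uniform in [-10, +10] HU, and linear motion blur with displacement
#' amplitude 1-3 voxels.
#'
#' @param noise_variance_hu2 noise variance (HU^2), >= 0.
#' @param calib_shift_range_hu length-2 shift range in HU.
#' @param motion_amp_range integer amplitude range in voxels (>= 1).
#' @param motion_direction unit 3-vector, or \code{"random"} for a
#'   random axis-aligned direction per call.
#' @param seed optional RNG seed applied by each artifact op.
#' @return list of class \code{"ArtifactSpec"}.
#' @export
artifactSpec <- function(noise_variance_hu2 = 15,
                         calib_shift_range_hu = c(-10, 10),
                         motion_amp_range = c(1L, 3L),
                         motion_direction = "random",
                         seed = NULL) {
  stopifnot(noise_variance_hu2 >= 0, length(calib_shift_range_hu) == 2L,
            motion_amp_range[1] >= 0)
  structure(list(noise_variance_hu2 = noise_variance_hu2,
                 calib_shift_range_hu = calib_shift_range_hu,
                 motion_amp_range = as.integer(motion_amp_range),
                 motion_direction = motion_direction, seed = seed),
            class = "ArtifactSpec")
}

maybe_seed <- function(spec, seed = NULL) {
  s <- if (!is.null(seed)) seed else spec$seed
  if (!is.null(s)) set.seed(s)
}

#' Additive Gaussian noise
#'
#' @param vol an \linkS4class{ImageVolume} (HU).
#' @param spec an \code{\link{artifactSpec}}.
#' @param seed optional seed overriding the spec's.
#' @return the noised volume.
#' @export
addGaussianNoise <- function(vol, spec = artifactSpec(), seed = NULL) {
  stopifnot(is(vol, "ImageVolume"))
  maybe_seed(spec, seed)
  if (spec$noise_variance_hu2 == 0) return(vol)
  v <- vol@values +
    array(rnorm(length(vol@values), 0, sqrt(spec$noise_variance_hu2)),
          dim = dim(vol@values))
  ImageVolume(v, vol@spacing, vol@origin)
}

#' Global calibration shift
#'
#' Adds one scalar drawn uniformly from the configured range to the
#' whole volume, emulating scanner calibration error. The drawn shift
#' is attached as attribute \code{"shift_hu"}.
#'
#' @inheritParams addGaussianNoise
#' @return the shifted volume.
#' @export
calibrationShift <- function(vol, spec = artifactSpec(), seed = NULL) {
  stopifnot(is(vol, "ImageVolume"))
  maybe_seed(spec, seed)
  c0 <- runif(1, spec$calib_shift_range_hu[1], spec$calib_shift_range_hu[2])
  out <- ImageVolume(vol@values + c0, vol@spacing, vol@origin)
  attr(out, "shift_hu") <- c0
  out
}

# Uniform line kernel of length amp+1 voxels; even lengths are
# symmetrized (mean of the two integer centerings) so the kernel is
# symmetric and mirror-padded convolution preserves total intensity.
motion_kernel <- function(amp) {
  L <- amp + 1L
  if (L <= 1L) return(list(taps = 1, offsets = 0L))
  if (L %% 2L == 1L) {
    r <- (L - 1L) %/% 2L
    list(taps = rep(1 / L, L), offsets = -r:r)
  } else {
    r <- L %/% 2L
    taps <- c(0.5 / L, rep(1 / L, L - 1L), 0.5 / L)
    list(taps = taps, offsets = -r:r)
  }
}

#' Linear motion blur
#'
#' Convolves with a normalized uniform line kernel of length
#' (amplitude + 1) voxels along the motion direction; mean intensity is
#' preserved. Axis-aligned directions use an exact 1D convolution;
#' oblique directions accumulate trilinearly shifted copies.
#'
#' @inheritParams addGaussianNoise
#' @param amplitude optional fixed amplitude (voxels); otherwise drawn
#'   uniformly from the spec's range.
#' @return the blurred volume.
#' @export
motionBlur <- function(vol, spec = artifactSpec(), seed = NULL,
                       amplitude = NULL) {
  stopifnot(is(vol, "ImageVolume"))
  maybe_seed(spec, seed)
  amp <- if (!is.null(amplitude)) as.integer(amplitude)
         else sample(spec$motion_amp_range[1]:spec$motion_amp_range[2], 1L)
  if (amp <= 0L) return(vol)
  dirn <- spec$motion_direction
  if (identical(dirn, "random")) {
    ax <- sample(0:2, 1L)
    dirn <- c(0, 0, 0)
    dirn[ax + 1L] <- sample(c(-1, 1), 1L)
  }
  dirn <- dirn / sqrt(sum(dirn^2))
  ker <- motion_kernel(amp)
  v <- vol@values
  ax <- which(abs(abs(dirn) - 1) < 1e-12)
  if (length(ax) == 1L) {
    off <- as.integer(round(ker$offsets * dirn[ax]))
    out <- .cx_axis_conv(v, dim(v), ax - 1L, ker$taps, off)
  } else {
    out <- array(0, dim = dim(v))
    for (j in seq_along(ker$taps)) {
      sh <- ker$offsets[j] * dirn
      out <- out + ker$taps[j] *
        .cx_warp_affine(v, dim(v), diag(3), sh, FALSE, TRUE, 0)
    }
  }
  res <- ImageVolume(out, vol@spacing, vol@origin)
  attr(res, "amplitude_vox") <- amp
  res
}

#' Deformation specification for robustness experiments
#'
#' @param scale_range isotropic scale factor range.
#' @param rotation_range_deg per-axis rotation range (degrees).
#' @param grid_size control-grid size per axis for grid distortion
#'   (border control points are fixed).
#' @param max_disp_mm maximum control-point displacement (mm); keep
#'   small relative to the tube radius so the field stays invertible.
#' @param seed optional seed.
#' @return list of class \code{"DeformationSpec"}.
#' @export
deformationSpec <- function(scale_range = c(0.9, 1.1),
                            rotation_range_deg = c(-10, 10),
                            grid_size = c(4L, 4L, 4L),
                            max_disp_mm = 4, seed = NULL) {
  structure(list(scale_range = scale_range,
                 rotation_range_deg = rotation_range_deg,
                 grid_size = as.integer(grid_size),
                 max_disp_mm = max_disp_mm, seed = seed),
            class = "DeformationSpec")
}

# smooth + resample + threshold for masks under a voxel-space pull-back
warp_mask <- function(mvals, warp_fun) {
  sm <- .cx_gaussian_blur(mvals, dim(mvals), c(1, 1, 1))
  w <- warp_fun(sm, cubic = FALSE)
  array(as.double(w >= 0.5), dim = dim(mvals))
}

#' Rigid/affine deformation of a full case
#'
#' Applies one similarity transform (isotropic scale + rotation about
#' the grid center): the image is resampled with cubic interpolation,
#' the mask with Gaussian-smoothed interpolation and 0.5 thresholding,
#' and the centerline points are mapped with the exact analytic
#' transform. Transforms that push the centerline outside the grid are
#' rejected.
#'
#' @param vol,mask,centerline a consistent case.
#' @param spec a \code{\link{deformationSpec}}.
#' @param seed optional seed.
#' @param scale,rotation_deg optional fixed parameters overriding the
#'   random draw.
#' @return list(volume, mask, centerline) transformed consistently.
#' @export
rigidDeform <- function(vol, mask, centerline, spec = deformationSpec(),
                        seed = NULL, scale = NULL, rotation_deg = NULL) {
  stopifnot(is(vol, "ImageVolume"), is(mask, "ProbabilityMask"),
            is(centerline, "Centerline"))
  maybe_seed(spec, seed)
  if (is.null(scale)) scale <- runif(1, spec$scale_range[1],
                                     spec$scale_range[2])
  if (is.null(rotation_deg))
    rotation_deg <- runif(3, spec$rotation_range_deg[1],
                          spec$rotation_range_deg[2])
  R <- rotmat3(rotation_deg)
  sp <- vol@spacing
  o <- vol@origin
  d <- dim(vol@values)
  ctr <- o + d * sp / 2
  # forward map (points): T(x) = ctr + scale * R (x - ctr)
  pts <- clPoints(centerline)
  newpts <- sweep(t(scale * (R %*% t(sweep(pts, 2, ctr)))), 2, ctr, `+`)
  v <- worldToVoxel(newpts, vol)
  if (any(attr(v, "outOfBounds")))
    stop("transform pushes the centerline out of the grid; ",
         "reduce scale/rotation magnitudes")
  identityT <- abs(scale - 1) < 1e-12 && all(abs(rotation_deg) < 1e-12)
  if (identityT)
    return(list(volume = vol, mask = mask, centerline = centerline))
  # voxel-space pull-back: v_in = A v + t
  M2 <- t(R) / scale
  A <- diag(1 / sp) %*% M2 %*% diag(sp)
  tt <- (ctr - o) / sp - 0.5 + diag(1 / sp) %*% M2 %*% (o - ctr + 0.5 * sp)
  wvol <- .cx_warp_affine(vol@values, d, A, as.numeric(tt), TRUE, TRUE, 0)
  wmask <- warp_mask(mask@values, function(x, cubic)
    .cx_warp_affine(x, d, A, as.numeric(tt), cubic, TRUE, 0))
  list(volume = ImageVolume(wvol, sp, o),
       mask = ProbabilityMask(wmask, sp, o),
       centerline = Centerline(newpts))
}

# dense displacement field (H,W,D,3; mm) from random control grid
make_disp_field <- function(spec, d, sp) {
  g <- spec$grid_size
  ctrl <- array(0, dim = c(g, 3L))
  inner <- lapply(g, function(n) if (n > 2) 2:(n - 1) else integer(0))
  nin <- prod(vapply(inner, length, 1L)) * 3L
  if (nin > 0) {
    vals <- runif(nin, -spec$max_disp_mm, spec$max_disp_mm)
    ctrl[inner[[1]], inner[[2]], inner[[3]], ] <-
      array(vals, dim = c(vapply(inner, length, 1L), 3L))
  }
  .cx_resize3d_fwd(ctrl, c(g, 3L), as.integer(d))
}

field_jacobian_ok <- function(u_vox) {
  d <- dim(u_vox)[1:3]
  gr <- function(a, comp) {
    x <- u_vox[, , , comp]
    dx <- array(0, dim = d)
    if (a == 1) { dx[-c(1, d[1]), , ] <- (x[-(1:2), , ] - x[1:(d[1] - 2), , ]) / 2 }
    if (a == 2) { dx[, -c(1, d[2]), ] <- (x[, -(1:2), ] - x[, 1:(d[2] - 2), ]) / 2 }
    if (a == 3) { dx[, , -c(1, d[3])] <- (x[, , -(1:2)] - x[, , 1:(d[3] - 2)]) / 2 }
    dx
  }
  J11 <- 1 + gr(1, 1); J12 <- gr(2, 1); J13 <- gr(3, 1)
  J21 <- gr(1, 2); J22 <- 1 + gr(2, 2); J23 <- gr(3, 2)
  J31 <- gr(1, 3); J32 <- gr(2, 3); J33 <- 1 + gr(3, 3)
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  min(det)
}

#' Smooth grid distortion of a full case
#'
#' A random displacement field is generated on a coarse control grid
#' (borders fixed), upsampled to the voxel grid, and checked for
#' invertibility (positive Jacobian determinant of the forward map);
#' folding fields are rejected. Centerline points move forward by the
#' field evaluated at their positions; the image is pulled back with
#' the small-displacement inverse approximation, cubic interpolation
#' for the image and smoothed-threshold interpolation for the mask.
#'
#' @inheritParams rigidDeform
#' @return list(volume, mask, centerline).
#' @export
gridDistortion <- function(vol, mask, centerline, spec = deformationSpec(),
                           seed = NULL) {
  stopifnot(is(vol, "ImageVolume"), is(mask, "ProbabilityMask"),
            is(centerline, "Centerline"))
  maybe_seed(spec, seed)
  d <- dim(vol@values)
  sp <- vol@spacing
  u_mm <- make_disp_field(spec, d, sp)
  if (max(abs(u_mm)) == 0)
    return(list(volume = vol, mask = mask, centerline = centerline))
  u_vox <- u_mm
  for (a in 1:3) u_vox[, , , a] <- u_mm[, , , a] / sp[a]
  jmin <- field_jacobian_ok(u_vox)
  if (jmin <= 0)
    stop(sprintf("displacement field folds (min Jacobian det %.3f); ",
                 jmin), "reduce max_disp_mm")
  # forward-move the centerline by the field at its points
  pts <- clPoints(centerline)
  un <- worldToNormalized(pts, vol)
  upts <- sampleTrilinear(u_mm, un)
  newpts <- pts + upts
  vchk <- worldToVoxel(newpts, vol)
  if (any(attr(vchk, "outOfBounds")))
    stop("distortion pushes the centerline out of the grid")
  neg <- -u_vox
  wvol <- .cx_warp_field(vol@values, d, neg, TRUE, TRUE, 0)
  wmask <- warp_mask(mask@values, function(x, cubic)
    .cx_warp_field(x, d, neg, cubic, TRUE, 0))
  list(volume = ImageVolume(wvol, sp, vol@origin),
       mask = ProbabilityMask(wmask, sp, vol@origin),
       centerline = Centerline(newpts))
}

flip_case <- function(case, axis) {
  d <- dim(case$volume@values)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- d[axis]:1
  flip_arr <- function(a) do.call(`[`, c(list(a), idx))
  sp <- case$volume@spacing
  o <- case$volume@origin
  pts <- clPoints(case$centerline)
  pts[, axis] <- 2 * o[axis] + d[axis] * sp[axis] - pts[, axis]
  list(volume = ImageVolume(flip_arr(case$volume@values), sp, o),
       mask = ProbabilityMask(flip_arr(case$mask@values), sp, o),
       centerline = Centerline(pts))
}

#' Training-time augmentation
#'
#' Random composition of axis flips, a small rigid transform, grid
#' distortion, additive Gaussian noise and Gaussian blur; mask and
#' centerline are transformed consistently with the image.
#'
#' @param case list(volume, mask, centerline).
#' @param seed integer seed (reproducible).
#' @param deform a \code{\link{deformationSpec}} for the geometric part.
#' @param artifacts an \code{\link{artifactSpec}} for the noise part.
#' @return the augmented case.
#' @export
trainingAugment <- function(case, seed,
                            deform = deformationSpec(max_disp_mm = 2),
                            artifacts = artifactSpec()) {
  set.seed(seed)
  for (axis in 1:3) if (runif(1) < 0.5) case <- flip_case(case, axis)
  cs <- tryCatch(
    rigidDeform(case$volume, case$mask, case$centerline, deform,
                seed = sample.int(1e9, 1)),
    error = function(e) case)
  case <- cs
  if (runif(1) < 0.5) {
    cs <- tryCatch(
      gridDistortion(case$volume, case$mask, case$centerline, deform,
                     seed = sample.int(1e9, 1)),
      error = function(e) case)
    case <- cs
  }
  if (runif(1) < 0.5)
    case$volume <- addGaussianNoise(case$volume, artifacts,
                                    seed = sample.int(1e9, 1))
  if (runif(1) < 0.5) {
    sig <- runif(1, 0.3, 1)
    case$volume <- ImageVolume(
      .cx_gaussian_blur(case$volume@values, dim(case$volume@values),
                        rep(sig, 3)),
      case$volume@spacing, case$volume@origin)
  }
  case
}
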