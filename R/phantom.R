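# Synthetic tubular CTA phantoms with analytic centerlines. Phantoms
# emulate unbranched aorta-like geometry on a 2 mm isotropic grid with
# sparse ground-truth annotations (~6 mm inter-point spacing), and are
# the package's stand-in for patient data in all tests.

#' Phantom specification
#'
#' Defines an unbranched tubular phantom: curve family, tube radius,
#' grid geometry, intensities and annotation density. The analytic
#' curve is centered in the grid and must fit with at least a 2-voxel
#' margin (including the tube radius); \code{\link{generateCurve}}
#' rejects specs that do not.
#'
#' @param curve_kind one of \code{"straight"}, \code{"arc"},
#'   \code{"aorta_like"} (arc plus two straight limbs, a candy-cane
#'   shape mimicking the thoracic aorta).
#' @param radius_mm tube radius in mm; length 1 (constant) or 2 (linear
#'   taper from start to end). Must be at least twice the largest voxel
#'   spacing so the tube is resolvable on the grid.
#' @param grid_shape integer(3) grid dimensions.
#' @param spacing_mm voxel spacing in mm (default 2 mm isotropic).
#' @param lumen_hu,background_hu intensities inside/outside the tube.
#' @param edge_softness_mm Gaussian blur width applied when rendering,
#'   emulating partial-volume edges; 0 disables.
#' @param gt_point_spacing_mm arclength spacing of ground-truth
#'   centerline points (default 6 mm, the annotation density regime of
#'   sparse manual aortic annotations).
#' @param length_mm straight-tube length (curve_kind "straight").
#' @param arc_radius_mm arc radius (kinds "arc", "aorta_like").
#' @param arc_angle_deg arc angle in degrees.
#' @param limb_mm straight-limb length for "aorta_like"; length 1 or 2.
#' @param rotation_deg numeric(3) extrinsic rotation (degrees about x,
#'   y, z) applied to the curve about the grid center.
#' @param seed integer seed recorded with the spec.
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(curve_kind = c("aorta_like", "straight", "arc"),
                        radius_mm = 10,
                        grid_shape = c(96L, 96L, 96L),
                        spacing_mm = c(2, 2, 2),
                        lumen_hu = 300, background_hu = 0,
                        edge_softness_mm = 1,
                        gt_point_spacing_mm = 6,
                        length_mm = 120,
                        arc_radius_mm = 55,
                        arc_angle_deg = 180,
                        limb_mm = 35,
                        rotation_deg = c(0, 0, 0),
                        seed = 1L) {
  curve_kind <- match.arg(curve_kind)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(limb_mm) == 1L) limb_mm <- rep(limb_mm, 2L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            all(spacing_mm > 0), all(radius_mm > 0),
            length(radius_mm) %in% 1:2,
            gt_point_spacing_mm > 0, edge_softness_mm >= 0)
  if (min(radius_mm) < 2 * max(spacing_mm))
    stop("radius_mm must be >= 2 x max(spacing_mm) so the tube is ",
         "resolvable on the grid")
  structure(list(curve_kind = curve_kind, radius_mm = radius_mm,
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 lumen_hu = lumen_hu, background_hu = background_hu,
                 edge_softness_mm = edge_softness_mm,
                 gt_point_spacing_mm = gt_point_spacing_mm,
                 length_mm = length_mm, arc_radius_mm = arc_radius_mm,
                 arc_angle_deg = arc_angle_deg, limb_mm = limb_mm,
                 rotation_deg = rotation_deg, seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Evaluate the analytic space curve at arclengths s (before placement).
curve_eval <- function(spec, s) {
  k <- spec$curve_kind
  if (k == "straight") {
    cbind(0, 0, s)
  } else if (k == "arc") {
    R <- spec$arc_radius_mm
    phi <- s / R
    cbind(R * sin(phi), 0, R * (1 - cos(phi)))
  } else {
    R <- spec$arc_radius_mm
    th <- spec$arc_angle_deg * pi / 180
    l1 <- spec$limb_mm[1]; l2 <- spec$limb_mm[2]
    p <- matrix(0, length(s), 3)
    seg1 <- s <= l1
    p[seg1, ] <- cbind(R, 0, s[seg1])
    inarc <- s > l1 & s <= l1 + R * th
    phi <- (s[inarc] - l1) / R
    p[inarc, ] <- cbind(R * cos(phi), 0, l1 + R * sin(phi))
    seg2 <- s > l1 + R * th
    if (any(seg2)) {
      t2 <- s[seg2] - l1 - R * th
      e <- c(R * cos(th), 0, l1 + R * sin(th))
      tg <- c(-sin(th), 0, cos(th))
      p[seg2, ] <- cbind(e[1] + t2 * tg[1], e[2], e[3] + t2 * tg[3])
    }
    p
  }
}

curve_length <- function(spec) {
  switch(spec$curve_kind,
    straight = spec$length_mm,
    arc = spec$arc_radius_mm * spec$arc_angle_deg * pi / 180,
    aorta_like = sum(spec$limb_mm) +
      spec$arc_radius_mm * spec$arc_angle_deg * pi / 180)
}

rotmat3 <- function(deg) {
  a <- deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Place the raw curve in the grid: rotate about its bounding-box center,
# then translate that center to the grid center.
curve_place <- function(spec, pts) {
  R <- rotmat3(spec$rotation_deg)
  ctr <- (apply(pts, 2, min) + apply(pts, 2, max)) / 2
  pts <- t(R %*% (t(pts) - ctr))
  extent <- spec$grid_shape * spec$spacing_mm
  sweep(pts, 2, extent / 2, `+`)
}

check_fit <- function(spec, pts) {
  extent <- spec$grid_shape * spec$spacing_mm
  margin <- 2 * spec$spacing_mm
  rmax <- max(spec$radius_mm)
  lo <- apply(pts, 2, min) - rmax
  hi <- apply(pts, 2, max) + rmax
  if (any(lo < margin) || any(hi > extent - margin))
    stop("curve does not fit inside the grid with a 2-voxel margin; ",
         "reduce curve size or enlarge the grid")
  invisible(TRUE)
}

#' Generate the analytic ground-truth centerline of a phantom
#'
#' Samples the spec's space curve at \code{gt_point_spacing_mm}
#' arclength intervals (points at \code{i * spacing}, so consecutive
#' gaps are exact), in world mm, ordered along the curve.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A \linkS4class{Centerline}.
#' @export
generateCurve <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  L <- curve_length(spec)
  n <- floor(L / spec$gt_point_spacing_mm + 1e-9)
  if (n < 1) stop("curve shorter than one ground-truth point spacing")
  s <- (0:n) * spec$gt_point_spacing_mm
  pts <- curve_place(spec, curve_eval(spec, s))
  check_fit(spec, pts)
  Centerline(pts)
}

# Dense polyline (step <= min(spacing)/4 along arclength) used for
# rasterization; returns points and per-point radius.
dense_curve <- function(spec, step = NULL) {
  if (is.null(step)) step <- min(spec$spacing_mm) / 4
  L <- curve_length(spec)
  n <- max(2L, ceiling(L / step))
  s <- seq(0, L, length.out = n + 1L)
  pts <- curve_place(spec, curve_eval(spec, s))
  r <- if (length(spec$radius_mm) == 2L)
    spec$radius_mm[1] + (spec$radius_mm[2] - spec$radius_mm[1]) * s / L
  else rep(spec$radius_mm, length(s))
  list(points = pts, radius = r)
}

#' Rasterize a tube around a centerline
#'
#' A voxel is foreground iff its center lies within the tube radius of
#' the curve, with distances measured to the input polyline densely
#' resampled at a step of at most a quarter voxel.
#'
#' @param curve a \linkS4class{Centerline} in world mm.
#' @param spec the \code{\link{phantomSpec}} providing grid and radius.
#' @param radius_mm optional radius override (length 1 or 2).
#' @param dense_step_mm optional resampling step override (mm).
#' @return A binary \linkS4class{ProbabilityMask}; the distance-to-curve
#'   field is attached as attribute \code{"dist_mm"}.
#' @export
rasterizeTube <- function(curve, spec, radius_mm = NULL,
                          dense_step_mm = NULL) {
  stopifnot(is(curve, "Centerline"), inherits(spec, "PhantomSpec"))
  step <- if (is.null(dense_step_mm)) min(spec$spacing_mm) / 4 else dense_step_mm
  r <- if (is.null(radius_mm)) spec$radius_mm else radius_mm
  pts <- clPoints(curve)
  dense <- resamplePolyline(Centerline(pts), step)
  L <- polylineLength(Centerline(pts))
  s <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  radii <- if (length(r) == 2L) r[1] + (r[2] - r[1]) * s / max(s, 1e-12)
           else rep(r[1], nrow(dense))
  res <- .cx_rasterize_tube(dense, radii, spec$grid_shape,
                            spec$spacing_mm, c(0, 0, 0))
  if (sum(res$mask) == 0L)
    warning("rasterized tube mask is empty (radius below voxel scale?)")
  m <- ProbabilityMask(array(as.double(res$mask), dim = spec$grid_shape),
                       spacing = spec$spacing_mm)
  attr(m, "dist_mm") <- res$dist
  m
}

#' Render a phantom HU volume from a mask
#'
#' Voxels take \code{lumen_hu} inside the mask and \code{background_hu}
#' outside; the binary image is then blurred with a Gaussian of width
#' \code{edge_softness_mm} to emulate partial-volume edges. Fully
#' deterministic.
#'
#' @param mask a binary \linkS4class{ProbabilityMask}.
#' @param spec the \code{\link{phantomSpec}}.
#' @return An \linkS4class{ImageVolume} in HU.
#' @export
renderVolume <- function(mask, spec) {
  stopifnot(is(mask, "ProbabilityMask"), inherits(spec, "PhantomSpec"))
  hu <- spec$background_hu +
    (spec$lumen_hu - spec$background_hu) * mask@values
  if (spec$edge_softness_mm > 0) {
    sig <- spec$edge_softness_mm / spec$spacing_mm
    hu <- .cx_gaussian_blur(hu, dim(hu), sig)
  }
  ImageVolume(hu, spacing = spec$spacing_mm, origin = mask@origin)
}

#' Build one phantom case from a spec
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A list with elements \code{volume}, \code{mask},
#'   \code{centerline}, \code{spec}.
#' @export
makePhantom <- function(spec) {
  cl <- generateCurve(spec)
  mask <- rasterizeTube(cl, spec)
  vol <- renderVolume(mask, spec)
  list(volume = vol, mask = mask, centerline = cl, spec = spec)
}

#' Randomized phantom parameter distribution
#'
#' Ranges from which \code{\link{makePhantomDataset}} draws per-case
#' curve parameters. The defaults mimic aortic scale on a 96^3 grid at
#' 2 mm spacing: arc radius 40-80 mm, tube radius 8-15 mm. Draws whose
#' curve does not fit the grid are rejected and redrawn.
#'
#' @param grid_shape integer(3) grid dims.
#' @param spacing_mm voxel spacing.
#' @param radius_range tube radius range (mm).
#' @param arc_radius_range arc radius range (mm).
#' @param arc_angle_range arc angle range (degrees).
#' @param limb_range straight-limb length range (mm).
#' @param rotation_max_deg max |rotation| per axis (degrees).
#' @param edge_softness_mm rendering blur width.
#' @param lumen_hu,background_hu intensities.
#' @return A list of class \code{"PhantomDistribution"}.
#' @export
phantomDistribution <- function(grid_shape = c(96L, 96L, 96L),
                                spacing_mm = c(2, 2, 2),
                                radius_range = c(8, 15),
                                arc_radius_range = c(40, 80),
                                arc_angle_range = c(150, 200),
                                limb_range = c(20, 45),
                                rotation_max_deg = 15,
                                edge_softness_mm = 1,
                                lumen_hu = 300, background_hu = 0) {
  structure(as.list(environment()), class = "PhantomDistribution")
}

#' Compact phantom distribution for 48^3 CPU-scale experiments
#'
#' Same family as \code{\link{phantomDistribution}} with curve scales
#' reduced to fit a 48^3 grid at 2 mm spacing.
#'
#' @return A \code{"PhantomDistribution"}.
#' @export
phantomDistributionTiny <- function() {
  phantomDistribution(grid_shape = c(48L, 48L, 48L),
                      radius_range = c(6, 9),
                      arc_radius_range = c(16, 26),
                      arc_angle_range = c(120, 200),
                      limb_range = c(8, 18),
                      rotation_max_deg = 20)
}

draw_spec <- function(dist, case_seed) {
  set.seed(case_seed)
  for (try in 1:200) {
    sp <- phantomSpec(
      curve_kind = "aorta_like",
      radius_mm = runif(1, dist$radius_range[1], dist$radius_range[2]),
      grid_shape = dist$grid_shape, spacing_mm = dist$spacing_mm,
      lumen_hu = dist$lumen_hu, background_hu = dist$background_hu,
      edge_softness_mm = dist$edge_softness_mm,
      arc_radius_mm = runif(1, dist$arc_radius_range[1],
                            dist$arc_radius_range[2]),
      arc_angle_deg = runif(1, dist$arc_angle_range[1],
                            dist$arc_angle_range[2]),
      limb_mm = runif(2, dist$limb_range[1], dist$limb_range[2]),
      rotation_deg = runif(3, -dist$rotation_max_deg,
                           dist$rotation_max_deg),
      seed = case_seed)
    ok <- tryCatch({
      check_fit(sp, curve_place(sp, curve_eval(sp, seq(0, curve_length(sp),
                                                       length.out = 64))))
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(sp)
  }
  stop("could not draw a phantom spec that fits the grid")
}

#' Generate a reproducible dataset of phantom cases
#'
#' Cases are independent draws from the parameter distribution; case i
#' is reproducible from (seed, i) alone. With \code{dir} set, volumes
#' and masks are written as NIfTI, centerlines as VTP and JSON, plus a
#' CSV manifest.
#'
#' @param n number of cases, >= 1.
#' @param dist a \code{\link{phantomDistribution}}.
#' @param seed integer RNG seed.
#' @param dir optional output directory for on-disk export.
#' @return A list of n cases (see \code{\link{makePhantom}}), with the
#'   manifest data frame attached as attribute \code{"manifest"}.
#' @export
makePhantomDataset <- function(n, dist = phantomDistribution(), seed = 1L,
                               dir = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cases <- vector("list", n)
  man <- data.frame(case = seq_len(n), seed = case_seeds,
                    n_gt_points = NA_integer_, radius_mm = NA_real_,
                    length_mm = NA_real_)
  for (i in seq_len(n)) {
    sp <- draw_spec(dist, case_seeds[i])
    cs <- makePhantom(sp)
    cases[[i]] <- cs
    man$n_gt_points[i] <- nPoints(cs$centerline)
    man$radius_mm[i] <- sp$radius_mm[1]
    man$length_mm[i] <- curve_length(sp)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeVolume(cs$volume, file.path(dir, sprintf("vol_%03d.nii.gz", i)))
      writeVolume(cs$mask, file.path(dir, sprintf("mask_%03d.nii.gz", i)))
      writeCenterline(cs$centerline, file.path(dir, sprintf("cl_%03d.vtp", i)))
      writeCenterline(cs$centerline, file.path(dir, sprintf("cl_%03d.json", i)))
    }
  }
  if (!is.null(dir))
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(cases, "manifest") <- man
  cases
}
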