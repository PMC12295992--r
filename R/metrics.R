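# Evaluation metrics: volumetric Dice for masks and 1D adaptations of
# Surface Dice / HD95 / ASSD for centerlines, plus the classical
# per-slice mass-centroid baseline. Canonical definitions used
# throughout: both polylines are resampled at 0.5 mm arclength steps;
# distances are point-to-segment distances to the opposite polyline;
# HD95/ASSD pool the directed distances from both sides; HD95 uses the
# linearly interpolated 95th percentile.

as_mask_array <- function(x) {
  if (is(x, "ProbabilityMask")) x@values else x
}

cl_mat <- function(x) {
  if (is(x, "Centerline")) clPoints(x) else rbind(x)
}

#' Volumetric Dice between two binary masks (percent)
#'
#' Probabilities are thresholded at 0.5. Two empty masks score 100 by
#' convention.
#'
#' @param mp predicted mask (ProbabilityMask or array).
#' @param mt ground-truth mask on the same grid.
#' @return Dice overlap in percent.
#' @export
volumetricDice <- function(mp, mt) {
  a <- as_mask_array(mp) > 0.5
  b <- as_mask_array(mt) > 0.5
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(100)
  100 * 2 * sum(a & b) / (sa + sb)
}

#' Resample a polyline at a fixed arclength step
#'
#' Places points at uniform arclength intervals of at most
#' \code{step_mm} along the chain (endpoints included, order
#' preserved): \code{n = ceiling(L / step)} equal intervals.
#'
#' @param cl a Centerline or N x 3 matrix.
#' @param step_mm maximum spacing between resampled points, > 0.
#' @return M x 3 matrix of points along the chain.
#' @export
resamplePolyline <- function(cl, step_mm) {
  stopifnot(step_mm > 0)
  p <- cl_mat(cl)
  if (nrow(p) == 1L) return(p)
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 0) return(p[1L, , drop = FALSE])
  n <- max(1L, ceiling(L / step_mm - 1e-9))
  s <- seq(0, L, length.out = n + 1L)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= length(cum)] <- length(cum) - 1L
  t <- (s - cum[idx]) / pmax(seg[idx], 1e-300)
  p[idx, , drop = FALSE] +
    (p[idx + 1L, , drop = FALSE] - p[idx, , drop = FALSE]) * t
}

#' Minimum distance from points to a polyline
#'
#' Point-to-segment distance over the chain of the polyline.
#'
#' @param points M x 3 matrix.
#' @param cl a Centerline or N x 3 matrix.
#' @return numeric(M) distances in the units of the inputs.
#' @export
pointPolylineDist <- function(points, cl) {
  .cx_point_polyline_dist(rbind(points), cl_mat(cl))
}

directed_dists <- function(cp, ct, step_mm) {
  P <- resamplePolyline(cp, step_mm)
  T <- resamplePolyline(ct, step_mm)
  list(dp = pointPolylineDist(P, ct), dt = pointPolylineDist(T, cp))
}

#' 1D Surface Dice between two centerlines (percent)
#'
#' Fraction of resampled points (both directions pooled) lying within
#' tolerance \code{tau_mm} of the opposite polyline.
#'
#' @param cp,ct the two centerlines (Centerline or matrix, world mm).
#' @param tau_mm tolerance in mm, > 0.
#' @param step_mm resampling step (default 0.5 mm).
#' @return Surface Dice in percent.
#' @export
surfaceDice1d <- function(cp, ct, tau_mm, step_mm = 0.5) {
  stopifnot(tau_mm > 0)
  d <- directed_dists(cp, ct, step_mm)
  100 * (sum(d$dp <= tau_mm) + sum(d$dt <= tau_mm)) /
    (length(d$dp) + length(d$dt))
}

#' 95th-percentile symmetric distance between centerlines (mm)
#'
#' Directed point-to-polyline distances from both resampled sets are
#' pooled; HD95 is their linearly interpolated 95th percentile.
#'
#' @inheritParams surfaceDice1d
#' @return HD95 in mm.
#' @export
hd95 <- function(cp, ct, step_mm = 0.5) {
  d <- directed_dists(cp, ct, step_mm)
  unname(quantile(c(d$dp, d$dt), 0.95, type = 7))
}

#' Average symmetric surface distance between centerlines (mm)
#'
#' Mean of the pooled directed point-to-polyline distances.
#'
#' @inheritParams surfaceDice1d
#' @return ASSD in mm.
#' @export
assd <- function(cp, ct, step_mm = 0.5) {
  d <- directed_dists(cp, ct, step_mm)
  mean(c(d$dp, d$dt))
}

# TRUE if the foreground of a binary 2D slice is a single 4-connected
# component (iterative dilation flood fill, vectorized).
slice_connected <- function(m) {
  n <- sum(m)
  if (n <= 1L) return(TRUE)
  seedij <- which(m, arr.ind = TRUE)[1L, ]
  reg <- matrix(FALSE, nrow(m), ncol(m))
  reg[seedij[1], seedij[2]] <- TRUE
  repeat {
    grown <- reg
    grown[-1, ] <- grown[-1, ] | reg[-nrow(m), ]
    grown[-nrow(m), ] <- grown[-nrow(m), ] | reg[-1, ]
    grown[, -1] <- grown[, -1] | reg[, -ncol(m)]
    grown[, -ncol(m)] <- grown[, -ncol(m)] | reg[, -1]
    grown <- grown & m
    if (sum(grown) == sum(reg)) break
    reg <- grown
  }
  sum(reg) == n
}

#' Mass-centroid centerline baseline
#'
#' The classical per-slice baseline: for each axial (third-axis) slice
#' with nonempty foreground, the centroid of the foreground voxels in
#' world mm, ordered by slice. Slices whose foreground splits into
#' several components (the failure mode of this baseline near an aortic
#' arch, where one slice cuts the vessel twice) are flagged via the
#' \code{"disconnected_slices"} attribute and a warning.
#'
#' @param mt a binary \linkS4class{ProbabilityMask}.
#' @return A \linkS4class{Centerline} of slice centroids.
#' @export
massCentroidBaseline <- function(mt) {
  stopifnot(is(mt, "ProbabilityMask"))
  m <- mt@values > 0.5
  if (!any(m)) stop("empty mask: no centerline can be extracted")
  d <- dim(m)
  pts <- NULL
  disc <- integer(0)
  for (k in seq_len(d[3])) {
    sl <- m[, , k]
    if (!any(sl)) next
    if (!slice_connected(sl)) disc <- c(disc, k)
    ij <- which(sl, arr.ind = TRUE)
    vox <- rbind(c(colMeans(ij) - 1, k - 1))  # 0-based voxel coords
    pts <- rbind(pts, voxelToWorld(vox, mt))
  }
  if (is.null(pts) || nrow(pts) < 2L)
    stop("mask foreground spans fewer than 2 axial slices")
  if (length(disc) > 0)
    warning(length(disc), " axial slice(s) have disconnected foreground; ",
            "centroids there may fall outside the lumen")
  cl <- Centerline(pts)
  attr(cl, "disconnected_slices") <- disc
  cl
}

#' Evaluate one case: mask and centerline metrics
#'
#' @param mp predicted mask, \code{mt} ground truth (same grid).
#' @param mt ground-truth binary mask.
#' @param cp predicted centerline, \code{ct} ground truth (world mm).
#' @param ct ground-truth centerline.
#' @return A list of class \code{"MetricReport"} with fields
#'   \code{vd_pct}, \code{sd1_pct}, \code{sd3_pct}, \code{hd95_mm},
#'   \code{assd_mm}.
#' @export
evaluateCase <- function(mp, mt, cp, ct) {
  rep <- list(vd_pct = volumetricDice(mp, mt),
              sd1_pct = surfaceDice1d(cp, ct, 1),
              sd3_pct = surfaceDice1d(cp, ct, 3),
              hd95_mm = hd95(cp, ct),
              assd_mm = assd(cp, ct))
  structure(rep, class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf(
    "VD %.2f%%  SD-1 %.2f%%  SD-3 %.2f%%  HD95 %.2f mm  ASSD %.2f mm\n",
    x$vd_pct, x$sd1_pct, x$sd3_pct, x$hd95_mm, x$assd_mm))
  invisible(x)
}

#' Aggregate per-case metric reports
#'
#' @param reports list of \code{MetricReport}s.
#' @return data.frame with per-metric mean and population standard
#'   deviation (the mean +/- sd reporting convention).
#' @export
aggregateReports <- function(reports) {
  m <- do.call(rbind, lapply(reports, function(r) unlist(r)))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(metric = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, pop_sd), row.names = NULL)
}
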