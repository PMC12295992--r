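# The composite training loss: voxel focal+dice term, Chamfer distance
# between point sets, squared-edge-length regularizer, point-in-lumen
# penalty with stop-gradient, and exponential-moving-average (EMA)
# normalization of the voxel and lumen terms. Exported functions are
# plain numeric; tape_* twins build the same expressions on the
# autodiff tape for training.

#' Voxel segmentation loss: focal + dice
#'
#' \code{-sum(Mt * (1 - Mp) * log(Mp)) - 2 * sum(Mt * Mp) / sum(Mt + Mp)}
#' with natural logarithm and probabilities clamped at \code{eps}. At a
#' perfect binary prediction the focal term vanishes and the dice term
#' is -1, so the loss tends to -1. An empty ground truth gives 0.
#'
#' @param mp predicted probabilities (ProbabilityMask or 3D array).
#' @param mt binary ground truth on the same grid.
#' @param eps clamp for log arguments (default 1e-7).
#' @param include_background also score the complementary background
#'   class (Mt_bg = 1 - Mt, Mp_bg = 1 - Mp), averaging the dice term
#'   over the two classes. The class sum of the loss is ambiguous for a
#'   single-channel output; the default scores the vessel class only,
#'   while training uses the two-class form so background confidence is
#'   also penalized. Both readings tend to -1 at a perfect prediction.
#' @return scalar loss.
#' @export
voxelLoss <- function(mp, mt, eps = 1e-7, include_background = FALSE) {
  p <- as_mask_array(mp)
  t <- as_mask_array(mt)
  stopifnot(identical(dim(p), dim(t)))
  dice_ratio <- function(tt, pp) {
    denom <- sum(tt + pp)
    if (denom > 0) sum(tt * pp) / denom else 0.5
  }
  focal <- -sum(t * (1 - p) * log(pmax(p, eps)))
  if (!include_background)
    return(focal - 2 * dice_ratio(t, p))
  focal_bg <- -sum((1 - t) * p * log(pmax(1 - p, eps)))
  focal + focal_bg - dice_ratio(t, p) - dice_ratio(1 - t, 1 - p)
}

#' Chamfer distance between two point sets
#'
#' Symmetric sum of nearest-neighbour Euclidean distances:
#' \code{sum_p min_t |p - t| + sum_t min_p |t - p|}. Unsquared norms by
#' default (set \code{squared = TRUE} for squared distances).
#'
#' @param cp,ct point sets (Centerline or N x 3 matrix), nonempty.
#' @param squared use squared Euclidean distances.
#' @return scalar >= 0; zero iff the two sets are equal as sets.
#' @export
chamferLoss <- function(cp, ct, squared = FALSE) {
  P <- cl_mat(cp); T <- cl_mat(ct)
  if (nrow(P) == 0 || nrow(T) == 0) stop("chamferLoss needs nonempty sets")
  d2 <- cross_dist2(P, T)
  if (squared) sum(apply(d2, 1, min)) + sum(apply(d2, 2, min))
  else sum(sqrt(apply(d2, 1, min))) + sum(sqrt(apply(d2, 2, min)))
}

# exact pairwise squared distances (per-coordinate differences, no
# cancellation: identical points give exactly zero)
cross_dist2 <- function(P, T) {
  outer(P[, 1], T[, 1], `-`)^2 + outer(P[, 2], T[, 2], `-`)^2 +
    outer(P[, 3], T[, 3], `-`)^2
}

#' Edge-length regularizer of a polyline
#'
#' Sum of squared consecutive-edge lengths. For fixed endpoints this is
#' minimized by uniformly spaced interior points, encouraging uniform
#' edge lengths. \code{mode = "variance"} gives the variance of edge
#' lengths instead.
#'
#' @param cp polyline (Centerline or N x 3 matrix), N >= 2.
#' @param mode \code{"sum_squared"} (default) or \code{"variance"}.
#' @return scalar >= 0.
#' @export
edgeLengthReg <- function(cp, mode = c("sum_squared", "variance")) {
  mode <- match.arg(mode)
  P <- cl_mat(cp)
  stopifnot(nrow(P) >= 2)
  e2 <- rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)
  if (mode == "sum_squared") sum(e2)
  else { e <- sqrt(e2); mean((e - mean(e))^2) }
}

#' Point-in-lumen penalty
#'
#' Samples the predicted probability mask at the centerline points with
#' trilinear interpolation and evaluates the focal+dice loss of the
#' sampled probabilities against an all-ones target, jointly over the
#' point set. Points deep inside the lumen (probability 1) give -1;
#' points outside are penalized. In training the sampled mask values
#' carry no gradient back to the voxel head (stop-gradient), while
#' gradients flow to the point coordinates through the interpolation
#' weights.
#'
#' @param cp_norm N x 3 point coordinates in the normalized [0,1] frame
#'   of the mask grid.
#' @param mp predicted probability mask (ProbabilityMask or 3D array).
#' @param eps clamp for log arguments.
#' @return scalar loss.
#' @export
pointLumenReg <- function(cp_norm, mp, eps = 1e-7) {
  m <- as_mask_array(mp)
  p <- .cx_gridsample_fwd(array(m, dim = c(dim(m), 1L)),
                          c(dim(m), 1L), rbind(cp_norm))[, 1]
  focal <- -sum((1 - p) * log(pmax(p, eps)))
  dice <- -2 * sum(p) / sum(1 + p)
  focal + dice
}

#' Initialize an exponential-moving-average loss tracker
#'
#' @param alpha smoothing factor in (0, 1), default 0.9.
#' @param init initial running value.
#' @return list of class \code{"EMAState"} with fields \code{alpha},
#'   \code{value}, \code{step}.
#' @export
emaInit <- function(alpha = 0.9, init = 0) {
  stopifnot(alpha >= 0, alpha < 1)
  structure(list(alpha = alpha, value = init, step = 0L),
            class = "EMAState")
}

#' Update an EMA tracker with a new loss value
#'
#' \code{running <- alpha * running + (1 - alpha) * new}. In training
#' the EMA expression itself is the applied term, with gradient flowing
#' only through the (1 - alpha)-weighted current loss.
#'
#' @param state an \code{\link{emaInit}} state.
#' @param value finite new loss value.
#' @return the updated state.
#' @export
emaUpdate <- function(state, value) {
  stopifnot(inherits(state, "EMAState"), is.finite(value))
  state$value <- state$alpha * state$value + (1 - state$alpha) * value
  state$step <- state$step + 1L
  state
}

#' Total multitask training loss
#'
#' Combines the EMA-tracked voxel loss, the Chamfer distance summed
#' over all centerline-decoder stage outputs (deep supervision), the
#' edge-length regularizer of the final polyline, and the EMA-tracked
#' point-in-lumen penalty. All centerline inputs are in the normalized
#' coordinate frame.
#'
#' @param mp predicted probability mask.
#' @param mt binary ground-truth mask.
#' @param cp_stages a single N x 3 matrix or list of per-stage
#'   matrices (normalized coordinates); the last is the prediction.
#' @param ct_norm ground-truth points in normalized coordinates.
#' @param ema_vox,ema_plr EMA states for the two tracked heads.
#' @param deep_supervision apply Chamfer to every stage (default) or
#'   only the final one.
#' @return list with the updated EMA states and a \code{breakdown} of
#'   class \code{"LossBreakdown"}: fields \code{l_vox}, \code{l_cd},
#'   \code{l_elr}, \code{l_plr} (as applied, i.e. EMA values for the
#'   tracked heads), raw values \code{l_vox_raw}, \code{l_plr_raw}, and
#'   \code{l_total} equal to the sum of the four applied terms.
#' @export
totalLoss <- function(mp, mt, cp_stages, ct_norm,
                      ema_vox = emaInit(), ema_plr = emaInit(),
                      deep_supervision = TRUE) {
  if (!is.list(cp_stages)) cp_stages <- list(cp_stages)
  final <- cp_stages[[length(cp_stages)]]
  l_vox_raw <- voxelLoss(mp, mt)
  ema_vox <- emaUpdate(ema_vox, l_vox_raw)
  l_cd <- if (deep_supervision)
    sum(vapply(cp_stages, chamferLoss, numeric(1), ct = ct_norm))
  else chamferLoss(final, ct_norm)
  l_elr <- edgeLengthReg(final)
  l_plr_raw <- pointLumenReg(final, mp)
  ema_plr <- emaUpdate(ema_plr, l_plr_raw)
  br <- structure(list(l_vox = ema_vox$value, l_cd = l_cd, l_elr = l_elr,
                       l_plr = ema_plr$value, l_vox_raw = l_vox_raw,
                       l_plr_raw = l_plr_raw,
                       l_total = ema_vox$value + l_cd + l_elr +
                         ema_plr$value),
                  class = "LossBreakdown")
  list(breakdown = br, ema_vox = ema_vox, ema_plr = ema_plr)
}

# ---- tape versions (training) ----------------------------------------

tape_voxel_loss <- function(mp_node, mt, eps = 1e-7,
                            include_background = FALSE) {
  mt_c <- ag_const(mt)
  focal <- ag_neg(ag_sum(ag_mul(mt_c, ag_mul(ag_sub(1, mp_node),
                                             ag_log_clamped(mp_node, eps)))))
  dice_fg <- ag_div(ag_sum(ag_mul(mt_c, mp_node)),
                    ag_sum(ag_add(mt_c, mp_node)))
  if (!include_background)
    return(ag_sub(focal, ag_mul(2, dice_fg)))
  mb <- ag_const(1 - mt)
  pb <- ag_sub(1, mp_node)
  focal_bg <- ag_neg(ag_sum(ag_mul(mb, ag_mul(mp_node,
                                              ag_log_clamped(pb, eps)))))
  dice_bg <- ag_div(ag_sum(ag_mul(mb, pb)), ag_sum(ag_add(mb, pb)))
  ag_sub(ag_add(focal, focal_bg), ag_add(dice_fg, dice_bg))
}

tape_chamfer <- function(cp_node, ct, squared = FALSE) {
  P <- cp_node$val
  d2 <- cross_dist2(P, ct)
  idx_p <- max.col(-d2, ties.method = "first")      # nearest t for each p
  idx_t <- max.col(-t(d2), ties.method = "first")   # nearest p for each t
  term <- function(diff_node) {
    rs <- ag_rowsums(ag_mul(diff_node, diff_node))
    if (squared) ag_sum(rs) else ag_sum(ag_sqrt_eps(rs))
  }
  d1 <- ag_sub(cp_node, ag_const(ct[idx_p, , drop = FALSE]))
  d2n <- ag_sub(ag_gather(cp_node, idx_t), ag_const(ct))
  ag_add(term(d1), term(d2n))
}

tape_edge_reg <- function(cp_node) {
  n <- nrow(cp_node$val)
  d <- ag_sub(ag_gather(cp_node, 2:n), ag_gather(cp_node, 1:(n - 1)))
  ag_sum(ag_mul(d, d))
}

tape_plr <- function(cp_node, mp_node, eps = 1e-7) {
  d <- dim(mp_node$val)
  m4 <- ag_reshape(ag_stopgrad(mp_node), c(d, 1L))
  p <- ag_gridsample(m4, cp_node)
  focal <- ag_neg(ag_sum(ag_mul(ag_sub(1, p), ag_log_clamped(p, eps))))
  dice <- ag_neg(ag_div(ag_mul(2, ag_sum(p)), ag_sum(ag_add(1, p))))
  ag_add(focal, dice)
}

# EMA training term: alpha * running (constant) + (1 - alpha) * current.
# Its value equals the updated EMA; only the current loss carries grad.
tape_ema_term <- function(raw_node, state) {
  ag_add(state$alpha * state$value, ag_mul(1 - state$alpha, raw_node))
}
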