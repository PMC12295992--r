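# The hybrid multitask network: a five-stage convolutional encoder
# (MBConv blocks: expand conv, squeeze-excitation, project conv), a
# U-Net style voxel decoder for the lumen mask, and a five-stage
# centerline decoder that alternates trilinear feature sampling with
# chain-graph convolution refinement of a point polyline. Forward
# passes are built on the autodiff tape so the same code serves
# training and inference.

#' Network configuration
#'
#' @param stage_channels five per-stage encoder channel counts; spatial
#'   dims halve (ceiling division) at each stage.
#' @param num_points number of centerline points predicted (>= 2).
#' @param neighbors_k neighbours sampled around each candidate point in
#'   the centerline decoder (>= 1); their predicted offsets are
#'   tanh-bounded to one stage-voxel.
#' @param rgconv_blocks residual graph-convolution blocks per stage.
#' @param stage1_absolute optional variant: the first (coarsest)
#'   refinement stage predicts absolute coordinates instead of residual
#'   offsets. Default FALSE (all stages residual with zero-initialized
#'   heads).
#' @param point_channels optional fixed width for the per-point
#'   feature vectors in the centerline decoder; the default (NULL)
#'   uses each stage's sampled-map channel count.
#' @param expand_ratio MBConv expansion ratio.
#' @param se_reduction squeeze-excitation channel reduction factor.
#' @return list of class \code{"NetworkConfig"}.
#' @export
networkConfig <- function(stage_channels = c(8L, 16L, 24L, 32L, 48L),
                          num_points = 96L, neighbors_k = 4L,
                          rgconv_blocks = 2L, point_channels = NULL,
                          stage1_absolute = FALSE,
                          expand_ratio = 2L,
                          se_reduction = 4L) {
  stopifnot(length(stage_channels) == 5L, all(stage_channels > 0),
            num_points >= 2L, neighbors_k >= 1L, rgconv_blocks >= 1L,
            is.null(point_channels) || point_channels >= 4L)
  structure(list(stage_channels = as.integer(stage_channels),
                 num_points = as.integer(num_points),
                 neighbors_k = as.integer(neighbors_k),
                 rgconv_blocks = as.integer(rgconv_blocks),
                 point_channels = if (is.null(point_channels)) NULL
                                  else as.integer(point_channels),
                 stage1_absolute = isTRUE(stage1_absolute),
                 expand_ratio = as.integer(expand_ratio),
                 se_reduction = as.integer(se_reduction)),
            class = "NetworkConfig")
}

#' Tiny CPU preset: channels (8,16,24,32,48), 32 points
#'
#' The canonical configuration for CPU-scale experiments on 48^3
#' phantoms.
#' @return a \code{\link{networkConfig}}.
#' @export
netPresetTiny <- function() {
  networkConfig(stage_channels = c(8L, 16L, 24L, 32L, 48L),
                num_points = 32L)
}

#' Full-scale preset: b0-like stage widths, 96 points
#'
#' Mirrors the EfficientNetV2-b0 stage layout and predicts 96 points.
#' @return a \code{\link{networkConfig}}.
#' @export
netPresetPaper <- function() {
  networkConfig(stage_channels = c(16L, 32L, 48L, 96L, 112L),
                num_points = 96L)
}

#' CenterlineNet: the multitask model object
#'
#' Holds the trainable parameters (autodiff leaf nodes) and the
#' \code{\link{networkConfig}}.
#' @slot params nested list of parameter nodes.
#' @slot config the network configuration.
#' @export
setClass("CenterlineNet",
         representation(params = "list", config = "list"))

setMethod("show", "CenterlineNet", function(object) {
  np <- sum(vapply(flatten_params(object@params),
                   function(p) length(p$val), numeric(1)))
  cat(sprintf(
    "CenterlineNet: channels [%s], %d centerline points, %d parameters\n",
    paste(object@config$stage_channels, collapse = ", "),
    object@config$num_points, np))
})

he_w <- function(nr, nc, fan_in, sd_scale = 1) {
  matrix(rnorm(nr * nc, 0, sd_scale * sqrt(2 / fan_in)), nr, nc)
}

conv_param <- function(k, cin, cout, sd_scale = 1) {
  list(w = ag_param(he_w(k^3 * cin, cout, k^3 * cin, sd_scale)),
       b = ag_param(numeric(cout)))
}

dw_param <- function(k, c) {
  list(w = ag_param(he_w(k^3, c, k^3)), b = ag_param(numeric(c)))
}

fc_param <- function(cin, cout, sd = NULL) {
  w <- if (is.null(sd)) he_w(cin, cout, cin)
       else matrix(rnorm(cin * cout, 0, sd), cin, cout)
  list(w = ag_param(w), b = ag_param(numeric(cout)))
}

norm_param <- function(c) {
  list(g = ag_param(rep(1, c)), b = ag_param(numeric(c)))
}

flatten_params <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (i in seq_along(p)) {
    q <- p[[i]]
    key <- if (prefix == "") nms[i] else paste0(prefix, ".", nms[i])
    if (inherits(q, "cx_node")) out[[key]] <- q
    else out <- c(out, flatten_params(q, key))
  }
  out
}

#' Create a multitask network with randomly initialized weights
#'
#' Coordinate heads are zero-initialized so each refinement stage
#' starts as the identity on the incoming polyline; neighbour heads
#' start near zero so initial neighbours coincide with their points.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param seed integer seed for weight initialization.
#' @return a \linkS4class{CenterlineNet}.
#' @export
createNetwork <- function(config = netPresetTiny(), seed = 42L) {
  stopifnot(inherits(config, "NetworkConfig"))
  set.seed(seed)
  ch <- config$stage_channels
  e <- config$expand_ratio
  enc <- vector("list", 5L)
  cin <- 1L
  for (s in 1:5) {
    cs <- ch[s]
    ce <- e * cs
    sq <- max(2L, cs %/% config$se_reduction)
    enc[[s]] <- list(
      down = conv_param(3L, cin, cs), down_n = norm_param(cs),
      expand = conv_param(1L, cs, ce), expand_n = norm_param(ce),
      dw = dw_param(3L, ce), dw_n = norm_param(ce),
      se1 = fc_param(ce, sq), se2 = fc_param(sq, ce),
      project = conv_param(1L, ce, cs), project_n = norm_param(cs))
    cin <- cs
  }
  dec <- vector("list", 4L)
  cprev <- ch[5]
  for (j in 1:4) {
    skip <- ch[5 - j]
    dec[[j]] <- list(
      conv1 = conv_param(3L, cprev + skip, skip), n1 = norm_param(skip),
      conv2 = conv_param(3L, skip, skip), n2 = norm_param(skip))
    cprev <- skip
  }
  # negative logit bias: the mask starts near empty, so the
  # foreground-only focal term grows it outward from true lumen voxels
  # instead of saturating the background
  head <- conv_param(1L, ch[1], 1L)
  head$b$val <- -2
  # full-resolution refinement: a small conv over the upsampled logit
  # and the input volume sharpens the boundary that the half-resolution
  # logit leaves blurred; zero-init second conv = pure upsampling start
  head_r1 <- conv_param(3L, 2L, 4L)
  head_r2 <- conv_param(1L, 4L, 1L)
  head_r2$w$val[] <- 0
  k <- config$neighbors_k
  cld <- vector("list", 5L)
  pyr_ch <- c(ch[5], ch[4], ch[3], ch[2], ch[1])
  for (s in 1:5) {
    cm <- pyr_ch[s]
    pc <- if (is.null(config$point_channels)) cm else config$point_channels
    rg <- vector("list", config$rgconv_blocks)
    for (b in seq_len(config$rgconv_blocks)) {
      rg[[b]] <- list(gc1 = fc_param(pc, pc), ln1 = norm_param(pc),
                      gc2 = fc_param(pc, pc), ln2 = norm_param(pc))
    }
    absolute <- s == 1L && config$stage1_absolute
    cld[[s]] <- list(
      nbr = fc_param(cm, 3L * k, sd = 0.01),
      # fuse consumes the point's own and neighbour features plus the
      # candidate coordinates, so offsets can be position-aware even
      # where the stage map is spatially coarse
      fuse = fc_param((k + 1L) * cm + 3L, pc),
      rg = rg,
      # offset heads are zero-initialized (stage starts as identity);
      # the absolute stage-1 head starts every point at the grid center
      coord = list(w = ag_param(matrix(
                     if (absolute) rnorm(pc * 3L, 0, 0.01) else 0,
                     pc, 3L)),
                   b = ag_param(rep(if (absolute) 0.5 else 0, 3L))))
  }
  new("CenterlineNet", params = list(enc = enc, dec = dec, head = head,
                                     head_r1 = head_r1,
                                     head_r2 = head_r2, cld = cld),
      config = unclass(config))
}

# symmetric-normalized chain adjacency (self + neighbours)
chain_adj_norm <- function(n) {
  A <- diag(n)
  if (n >= 2) {
    idx <- cbind(1:(n - 1), 2:n)
    A[idx] <- 1
    A[idx[, 2:1, drop = FALSE]] <- 1
  }
  d <- rowSums(A)
  A * outer(1 / sqrt(d), 1 / sqrt(d))
}

conv_block <- function(x, p, n, k, stride, pad, act) {
  h <- ag_conv3d(x, p$w, p$b, k, stride, pad)
  h <- ag_instnorm(h, n$g, n$b)
  act(h)
}

encoder_tape <- function(net, xnode) {
  p <- net@params$enc
  out <- vector("list", 5L)
  h <- xnode
  for (s in 1:5) {
    ps <- p[[s]]
    h <- conv_block(h, ps$down, ps$down_n, 3L, 2L, 1L, ag_silu)
    r <- h
    m <- conv_block(h, ps$expand, ps$expand_n, 1L, 1L, 0L, ag_silu)
    m <- ag_dwconv3d(m, ps$dw$w, ps$dw$b, 3L, 1L, 1L)
    m <- ag_silu(ag_instnorm(m, ps$dw_n$g, ps$dw_n$b))
    v <- ag_gap(m)
    v2 <- ag_reshape(v, c(1L, length(v$val)))
    v2 <- ag_silu(ag_addrow(ag_mm(v2, ps$se1$w), ps$se1$b))
    v2 <- ag_sigmoid(ag_addrow(ag_mm(v2, ps$se2$w), ps$se2$b))
    m <- ag_chscale(m, ag_reshape(v2, ncol(v2$val)))
    m <- ag_instnorm(ag_conv3d(m, ps$project$w, ps$project$b, 1L, 1L, 0L),
                     ps$project_n$g, ps$project_n$b)
    h <- ag_add(m, r)
    out[[s]] <- h
  }
  out
}

voxel_decoder_tape <- function(net, enc, full_dims, xin) {
  p <- net@params$dec
  x <- enc[[5]]
  pyr <- list(enc[[5]])
  for (j in 1:4) {
    skip <- enc[[5 - j]]
    x <- ag_resize3d(x, dim(skip$val)[1:3])
    x <- ag_concat_ch(x, skip)
    x <- conv_block(x, p[[j]]$conv1, p[[j]]$n1, 3L, 1L, 1L, ag_relu)
    x <- conv_block(x, p[[j]]$conv2, p[[j]]$n2, 3L, 1L, 1L, ag_relu)
    pyr[[j + 1L]] <- x
  }
  logits <- ag_conv3d(x, net@params$head$w, net@params$head$b, 1L, 1L, 0L)
  logits_up <- ag_resize3d(logits, full_dims)
  h <- ag_silu(ag_conv3d(ag_concat_ch(logits_up, xin),
                         net@params$head_r1$w, net@params$head_r1$b,
                         3L, 1L, 1L))
  refine <- ag_conv3d(h, net@params$head_r2$w, net@params$head_r2$b,
                      1L, 1L, 0L)
  prob <- ag_reshape(ag_sigmoid(ag_add(logits_up, refine)), full_dims)
  list(pyramid = pyr, prob = prob)
}

rgconv_tape <- function(x, p, Ahat) {
  h <- ag_layernorm(ag_silu(ag_addrow(ag_mm(ag_mm(Ahat, x), p$gc1$w),
                                      p$gc1$b)), p$ln1$g, p$ln1$b)
  h <- ag_layernorm(ag_silu(ag_addrow(ag_mm(ag_mm(Ahat, h), p$gc2$w),
                                      p$gc2$b)), p$ln2$g, p$ln2$b)
  ag_add(x, h)
}

centerline_decoder_tape <- function(net, pyramid, init_coords) {
  cfg <- net@config
  k <- cfg$neighbors_k
  n <- nrow(init_coords)
  Ahat <- ag_const(chain_adj_norm(n))
  coords <- as_node(init_coords)
  p <- net@params$cld
  stages <- vector("list", 5L)
  for (s in 1:5) {
    fmap <- pyramid[[s]]
    sdim <- dim(fmap$val)[1:3]
    bound <- matrix(rep(1 / sdim, each = n), n, 3)
    ptsf <- ag_gridsample(fmap, coords)
    off <- ag_tanh(ag_addrow(ag_mm(ptsf, p[[s]]$nbr$w), p[[s]]$nbr$b))
    fused <- ptsf
    for (j in seq_len(k)) {
      oj <- ag_cols(off, (3L * (j - 1L) + 1L):(3L * j))
      nbr_c <- ag_add(coords, ag_mul(oj, ag_const(bound)))
      fused <- ag_cbind2(fused, ag_gridsample(fmap, nbr_c))
    }
    fused <- ag_cbind2(fused, coords)
    pf <- ag_addrow(ag_mm(fused, p[[s]]$fuse$w), p[[s]]$fuse$b)
    for (b in seq_along(p[[s]]$rg))
      pf <- rgconv_tape(pf, p[[s]]$rg[[b]], Ahat)
    offc <- ag_addrow(ag_mm(ag_mm(Ahat, pf), p[[s]]$coord$w),
                      p[[s]]$coord$b)
    if (s == 1L && isTRUE(cfg$stage1_absolute))
      coords <- ag_clamp(offc, 0, 1)
    else
      coords <- ag_clamp(ag_add(coords, offc), 0, 1)
    stages[[s]] <- coords
  }
  stages
}

check_input_dims <- function(d) {
  if (length(d) != 3L || any(d < 32L))
    stop("network input must be a 3D volume with all axes >= 32 ",
         "(got ", paste(d, collapse = "x"), ")")
}

as_norm_array <- function(vol) {
  v <- if (is(vol, "ImageVolume")) vol@values else vol
  stopifnot(is.array(v))
  v
}

# full tape forward; input: 3D array in [0,1], init polyline (normalized)
forward_tape <- function(net, varr, init_coords) {
  d <- dim(varr)
  check_input_dims(d)
  xnode <- ag_const(array(varr, dim = c(d, 1L)))
  enc <- encoder_tape(net, xnode)
  vd <- voxel_decoder_tape(net, enc, d, xnode)
  stages <- centerline_decoder_tape(net, vd$pyramid, init_coords)
  list(enc = enc, pyramid = vd$pyramid, prob = vd$prob, stages = stages)
}

#' Random polyline initialization in the normalized frame
#'
#' Default (\code{mode = "segment"}): two endpoints drawn uniformly in
#' [0.2, 0.8]^3 with \code{num_points} equally spaced points between
#' them. \code{mode = "uniform"} draws all points i.i.d. uniform in
#' [0.2, 0.8]^3.
#'
#' @param seed integer seed.
#' @param num_points number of points (>= 2).
#' @param mode \code{"segment"} or \code{"uniform"}.
#' @return N x 3 matrix of normalized coordinates in [0, 1]^3.
#' @export
initPolyline <- function(seed, num_points, mode = c("segment", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(num_points >= 2)
  # draw under a local RNG state: callers' random streams (training
  # loops, robustness drivers) must not be reset by inference
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (mode == "segment") {
    a <- runif(3, 0.2, 0.8)
    b <- runif(3, 0.2, 0.8)
    t <- seq(0, 1, length.out = num_points)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
          a[3] + t * (b[3] - a[3]))
  } else {
    matrix(runif(3 * num_points, 0.2, 0.8), num_points, 3)
  }
}

#' Run the encoder on a normalized volume
#'
#' @param net a \linkS4class{CenterlineNet}.
#' @param vol a 3D array or ImageVolume with values in [0, 1]; all axes
#'   must be >= 32.
#' @return list of five feature arrays (H, W, D, C), stage s downsampled
#'   by 2^s (ceiling division).
#' @export
encoderForward <- function(net, vol) {
  varr <- as_norm_array(vol)
  d <- dim(varr)
  check_input_dims(d)
  enc <- encoder_tape(net, ag_const(array(varr, dim = c(d, 1L))))
  lapply(enc, function(n) n$val)
}

#' Run encoder + voxel decoder, returning the probability mask
#'
#' @inheritParams encoderForward
#' @return list with \code{prob} (3D array in (0,1), same grid as the
#'   input) and \code{pyramid} (five feature arrays, coarse to fine).
#' @export
voxelDecoderForward <- function(net, vol) {
  varr <- as_norm_array(vol)
  d <- dim(varr)
  check_input_dims(d)
  xnode <- ag_const(array(varr, dim = c(d, 1L)))
  enc <- encoder_tape(net, xnode)
  vd <- voxel_decoder_tape(net, enc, d, xnode)
  list(prob = array(vd$prob$val, dim = d),
       pyramid = lapply(vd$pyramid, function(n) n$val))
}

#' Run the centerline decoder
#'
#' @inheritParams encoderForward
#' @param init_coords N x 3 polyline in normalized [0,1]^3 coordinates
#'   (defaults to \code{initPolyline(0, num_points)}).
#' @return list of five N x 3 matrices (per-stage polylines, normalized
#'   coordinates); the last is the prediction.
#' @export
centerlineDecoderForward <- function(net, vol, init_coords = NULL) {
  varr <- as_norm_array(vol)
  if (is.null(init_coords))
    init_coords <- initPolyline(0L, net@config$num_points)
  stopifnot(nrow(init_coords) == net@config$num_points)
  fw <- forward_tape(net, varr, init_coords)
  lapply(fw$stages, function(n) n$val)
}

#' Trilinear feature sampling at normalized coordinates
#'
#' Interpolates a feature map over the 8 surrounding voxel centers;
#' out-of-range coordinates are clamped to the border.
#'
#' @param fmap 3D (H,W,D) or 4D (H,W,D,C) array.
#' @param coords M x 3 matrix of normalized [0,1] coordinates.
#' @return M x C matrix of sampled features.
#' @export
sampleTrilinear <- function(fmap, coords) {
  if (length(dim(fmap)) == 3L) dim(fmap) <- c(dim(fmap), 1L)
  .cx_gridsample_fwd(fmap, dim(fmap), rbind(coords))
}

#' Full multitask forward pass
#'
#' One pass predicts both the lumen probability mask (input grid) and
#' the centerline polyline, converted to world mm. The predicted
#' polyline always has \code{num_points} points connected as a chain;
#' no post-processing is applied.
#'
#' @param net a \linkS4class{CenterlineNet}.
#' @param vol an \linkS4class{ImageVolume} with values already
#'   windowed to [0, 1] (see \code{\link{applyWindow}}).
#' @param init_seed seed for the random polyline initialization
#'   (fixed default makes inference deterministic).
#' @return list with \code{mask} (\linkS4class{ProbabilityMask}),
#'   \code{centerline} (\linkS4class{Centerline}, world mm), and
#'   \code{stages} (per-stage normalized polylines).
#' @export
networkForward <- function(net, vol, init_seed = 0L) {
  stopifnot(is(net, "CenterlineNet"), is(vol, "ImageVolume"))
  init <- initPolyline(init_seed, net@config$num_points)
  fw <- forward_tape(net, vol@values, init)
  d <- dim(vol@values)
  prob <- array(fw$prob$val, dim = d)
  mask <- ProbabilityMask(prob, spacing = vol@spacing, origin = vol@origin)
  final <- fw$stages[[5]]$val
  cl <- Centerline(normalizedToWorld(final, vol))
  list(mask = mask, centerline = cl,
       stages = lapply(fw$stages, function(n) n$val))
}
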