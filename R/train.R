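# Training loop (AdamW with decoupled weight decay and gradient
# clipping), checkpointing, inference, and the robustness experiment
# driver.

#' Training configuration
#'
#' Defaults are the CPU-scale configuration: AdamW with learning rate
#' 1e-3, 10 epochs of 50 iterations, batch size 2. The full-scale
#' schedule (80 epochs x 1000 iterations) is the same optimizer scaled
#' up.
#'
#' @param learning_rate AdamW learning rate.
#' @param epochs number of epochs.
#' @param iterations_per_epoch iterations per epoch.
#' @param batch_size cases per iteration.
#' @param weight_decay decoupled weight decay coefficient.
#' @param lr_schedule \code{"cosine"} (default; decays to 5\% of the
#'   base rate over the run, stabilizing the late phase of short
#'   schedules) or \code{"constant"}.
#' @param clip_norm global gradient-norm clip (stability guard).
#' @param point_lr_mult learning-rate multiplier for the centerline
#'   decoder's parameters (default 1; large values destabilize the
#'   zero-initialized coordinate heads).
#' @param init_modes polyline initializer families sampled uniformly
#'   during training (default \code{"segment"}, matching inference;
#'   adding \code{"uniform"} widens the initialization distribution
#'   but slows convergence on short schedules).
#' @param weight_avg_frac average the weights over the trailing
#'   fraction of iterations (Polyak tail averaging) and return the
#'   averaged network; 0 disables. Smooths the parameter noise of
#'   short schedules; the training log and resume state always use the
#'   raw (non-averaged) weights.
#' @param alpha EMA smoothing for loss normalization.
#' @param deep_supervision apply Chamfer to every decoder stage.
#' @param chamfer_squared train with squared Chamfer distances instead
#'   of unsquared (default unsquared: squared loses the constant-pull
#'   precision gradient near the curve).
#' @param inits_per_sample random polyline initializations refined per
#'   drawn volume each iteration; their centerline losses are averaged.
#'   The feature pyramid is computed once per volume, so extra
#'   initializations are nearly free and average out the high gradient
#'   variance that single random initializations cause.
#' @param voxel_background include the complementary background class
#'   in the voxel loss (see \code{\link{voxelLoss}}); default TRUE.
#' @param loss_mode \code{"ema"} (the EMA expression is the applied
#'   term) or \code{"normalize_by_ema"} (raw loss divided by the
#'   detached running value).
#' @param augment probability of applying \code{\link{trainingAugment}}
#'   to a drawn case (logical TRUE/FALSE maps to 1/0; default off).
#'   The full augmentation suite (flips, small rigid and grid
#'   deformations, noise, blur) pays off on long schedules; on the
#'   short CPU schedule it slows convergence markedly, so the canonical
#'   configuration trains on clean phantoms.
#' @param window a \code{\link{windowSpec}} for input normalization.
#' @param seed RNG seed.
#' @param checkpoint_dir optional directory for diagnostic checkpoints.
#' @return list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(learning_rate = 1e-3, epochs = 10L,
                        iterations_per_epoch = 50L, batch_size = 2L,
                        weight_decay = 1e-4,
                        lr_schedule = c("cosine", "constant"),
                        clip_norm = 1.0, point_lr_mult = 1,
                        weight_avg_frac = 0.2,
                        alpha = 0.9, deep_supervision = TRUE,
                        chamfer_squared = FALSE,
                        inits_per_sample = 1L,
                        voxel_background = TRUE,
                        init_modes = "segment",
                        loss_mode = c("ema", "normalize_by_ema"),
                        augment = 0,
                        window = windowSpec(), seed = 1L,
                        checkpoint_dir = NULL) {
  loss_mode <- match.arg(loss_mode)
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(learning_rate > 0, epochs >= 1, iterations_per_epoch >= 1,
            batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, lr_schedule = lr_schedule,
                 clip_norm = clip_norm, point_lr_mult = point_lr_mult,
                 init_modes = init_modes,
                 weight_avg_frac = weight_avg_frac,
                 alpha = alpha, deep_supervision = deep_supervision,
                 chamfer_squared = isTRUE(chamfer_squared),
                 inits_per_sample = as.integer(inits_per_sample),
                 voxel_background = voxel_background,
                 loss_mode = loss_mode, augment = as.numeric(augment),
                 window = window, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "TrainConfig")
}

prepare_case <- function(case, window) {
  list(varr = applyWindow(case$volume, window)@values,
       mt = case$mask@values,
       ct_norm = worldToNormalized(clPoints(case$centerline),
                                   case$volume),
       raw = case)
}

#' Train the multitask network
#'
#' Minimizes the composite loss (EMA-tracked voxel focal+dice, Chamfer
#' over all decoder stages, edge-length regularizer, EMA-tracked
#' point-in-lumen penalty) with AdamW. Per-iteration loss components
#' and EMA states are logged. Training aborts with a diagnostic
#' checkpoint if the loss turns non-finite.
#'
#' @param net a \linkS4class{CenterlineNet} (modified in place and
#'   returned).
#' @param dataset list of cases (\code{volume}, \code{mask},
#'   \code{centerline}).
#' @param config a \code{\link{trainConfig}}.
#' @param resume optional checkpoint (from \code{\link{saveCheckpoint}}
#'   / \code{\link{loadCheckpoint}}) to continue from.
#' @return list with \code{net}, \code{log} (one row per iteration),
#'   \code{ema_vox}, \code{ema_plr}, \code{opt} (optimizer state) and
#'   \code{rng} (RNG state), suitable for checkpointing.
#' @export
trainNetwork <- function(net, dataset, config = trainConfig(),
                         resume = NULL) {
  stopifnot(is(net, "CenterlineNet"))
  plist <- flatten_params(net@params)
  nprm <- length(plist)
  if (is.null(resume)) {
    set.seed(config$seed)
    opt <- list(m = lapply(plist, function(p) p$val * 0),
                v = lapply(plist, function(p) p$val * 0), t = 0L)
    ema_vox <- emaInit(config$alpha)
    ema_plr <- emaInit(config$alpha)
    start_iter <- 0L
  } else {
    rp <- if (!is.null(resume$params_raw)) resume$params_raw else resume$params
    for (nm in names(plist)) plist[[nm]]$val <- rp[[nm]]
    opt <- resume$opt
    ema_vox <- resume$ema_vox
    ema_plr <- resume$ema_plr
    start_iter <- resume$iter
    assign(".Random.seed", resume$rng, envir = globalenv())
  }
  prep <- lapply(dataset, prepare_case, window = config$window)
  total_iters <- config$epochs * config$iterations_per_epoch
  log <- vector("list", total_iters)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  avg_frac <- if (is.null(config$weight_avg_frac)) 0 else config$weight_avg_frac
  avg_from <- total_iters - max(1L, ceiling(avg_frac * total_iters)) + 1L
  avg <- NULL; avg_n <- 0L
  for (it in seq_len(total_iters)) {
    for (p in plist) p$grad <- NULL
    idx <- sample.int(length(prep), config$batch_size,
                      replace = length(prep) < config$batch_size)
    raw_vox <- raw_cd <- raw_elr <- raw_plr <- 0
    for (ci in idx) {
      pc <- prep[[ci]]
      if (config$augment > 0 && runif(1) < config$augment) {
        aug <- trainingAugment(pc$raw, seed = sample.int(1e9, 1))
        pc <- prepare_case(aug, config$window)
      }
      d <- dim(pc$varr)
      check_input_dims(d)
      xnode <- ag_const(array(pc$varr, dim = c(d, 1L)))
      enc <- encoder_tape(net, xnode)
      vd <- voxel_decoder_tape(net, enc, d, xnode)
      l_vox <- tape_voxel_loss(vd$prob, pc$mt,
                               include_background = isTRUE(config$voxel_background))
      # one feature pyramid, several refined initializations
      m_init <- max(1L, config$inits_per_sample)
      l_cd <- l_elr <- l_plr <- NULL
      for (mi in seq_len(m_init)) {
        imode <- config$init_modes[sample.int(length(config$init_modes), 1)]
        init <- initPolyline(sample.int(.Machine$integer.max - 1L, 1),
                             net@config$num_points, mode = imode)
        stages <- centerline_decoder_tape(net, vd$pyramid, init)
        final <- stages[[5]]
        cd_stages <- if (config$deep_supervision) stages else list(final)
        cd_m <- Reduce(ag_add, lapply(cd_stages, tape_chamfer,
                                      ct = pc$ct_norm,
                                      squared = isTRUE(config$chamfer_squared)))
        elr_m <- tape_edge_reg(final)
        plr_m <- tape_plr(final, vd$prob)
        l_cd <- if (is.null(l_cd)) cd_m else ag_add(l_cd, cd_m)
        l_elr <- if (is.null(l_elr)) elr_m else ag_add(l_elr, elr_m)
        l_plr <- if (is.null(l_plr)) plr_m else ag_add(l_plr, plr_m)
      }
      l_cd <- ag_mul(l_cd, 1 / m_init)
      l_elr <- ag_mul(l_elr, 1 / m_init)
      l_plr <- ag_mul(l_plr, 1 / m_init)
      if (config$loss_mode == "ema") {
        term_vox <- tape_ema_term(l_vox, ema_vox)
        term_plr <- tape_ema_term(l_plr, ema_plr)
      } else {
        term_vox <- ag_mul(l_vox, 1 / max(abs(ema_vox$value), 1e-3))
        term_plr <- ag_mul(l_plr, 1 / max(abs(ema_plr$value), 1e-3))
      }
      total <- ag_add(ag_add(term_vox, l_cd), ag_add(l_elr, term_plr))
      if (!is.finite(total$val)) {
        ck <- file.path(if (is.null(config$checkpoint_dir)) tempdir()
                        else config$checkpoint_dir,
                        "diverged_checkpoint.rds")
        saveCheckpoint(list(net = net, opt = opt, ema_vox = ema_vox,
                            ema_plr = ema_plr, iter = start_iter + it,
                            rng = get(".Random.seed",
                                      envir = globalenv())), ck)
        stop("training diverged (non-finite loss) at iteration ",
             start_iter + it, "; diagnostic checkpoint at ", ck)
      }
      ag_backward(ag_mul(total, 1 / config$batch_size))
      raw_vox <- raw_vox + l_vox$val / config$batch_size
      raw_cd <- raw_cd + l_cd$val / config$batch_size
      raw_elr <- raw_elr + l_elr$val / config$batch_size
      raw_plr <- raw_plr + l_plr$val / config$batch_size
    }
    ema_vox <- emaUpdate(ema_vox, raw_vox)
    ema_plr <- emaUpdate(ema_plr, raw_plr)
    # global-norm clip + AdamW step
    sq <- 0
    for (p in plist) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
    scale <- if (sqrt(sq) > config$clip_norm)
      config$clip_norm / (sqrt(sq) + 1e-12) else 1
    opt$t <- opt$t + 1L
    bc1 <- 1 - b1^opt$t
    bc2 <- 1 - b2^opt$t
    lr <- if (identical(config$lr_schedule, "constant")) config$learning_rate
          else config$learning_rate *
            (0.05 + 0.95 * 0.5 * (1 + cos(pi * it / total_iters)))
    plm <- if (is.null(config$point_lr_mult)) 1 else config$point_lr_mult
    for (nm in names(plist)) {
      p <- plist[[nm]]
      g <- if (is.null(p$grad)) p$val * 0 else p$grad * scale
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
      step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
      lr_p <- if (startsWith(nm, "cld.")) lr * plm else lr
      p$val <- p$val - lr_p * (step + config$weight_decay * p$val)
      p$grad <- NULL
    }
    if (avg_frac > 0 && it >= avg_from) {
      if (is.null(avg)) avg <- lapply(plist, function(p) p$val * 0)
      for (nm in names(plist)) avg[[nm]] <- avg[[nm]] + plist[[nm]]$val
      avg_n <- avg_n + 1L
    }
    log[[it]] <- data.frame(iter = start_iter + it, l_vox = raw_vox,
                            l_cd = raw_cd, l_elr = raw_elr,
                            l_plr = raw_plr,
                            l_total = ema_vox$value + raw_cd + raw_elr +
                              ema_plr$value,
                            ema_vox = ema_vox$value,
                            ema_plr = ema_plr$value)
  }
  params_raw <- lapply(plist, function(p) p$val)
  if (!is.null(avg) && avg_n > 0)
    for (nm in names(plist)) plist[[nm]]$val <- avg[[nm]] / avg_n
  list(net = net, log = do.call(rbind, log), ema_vox = ema_vox,
       ema_plr = ema_plr, opt = opt, iter = start_iter + total_iters,
       params_raw = params_raw,
       rng = get(".Random.seed", envir = globalenv()))
}

#' Save a training checkpoint
#'
#' Stores plain parameter arrays, the network configuration, optimizer
#' and EMA state, and the RNG state, so training can resume exactly.
#'
#' @param state the list returned by \code{\link{trainNetwork}} (or a
#'   list with at least \code{net}).
#' @param path output .rds path.
#' @return the path, invisibly.
#' @export
saveCheckpoint <- function(state, path) {
  net <- state$net
  plist <- flatten_params(net@params)
  saveRDS(list(params = lapply(plist, function(p) p$val),
               params_raw = state$params_raw,
               config = net@config, opt = state$opt,
               ema_vox = state$ema_vox, ema_plr = state$ema_plr,
               iter = state$iter, rng = state$rng), path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path an .rds checkpoint from \code{\link{saveCheckpoint}}.
#' @return list with a reconstructed \code{net} plus the stored
#'   optimizer/EMA/RNG state; pass it to \code{trainNetwork(resume=)}.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(networkConfig, ck$config[c("stage_channels", "num_points",
                                            "neighbors_k", "rgconv_blocks",
                                            "point_channels",
                                            "stage1_absolute",
                                            "expand_ratio", "se_reduction")])
  net <- createNetwork(cfg, seed = 0L)
  plist <- flatten_params(net@params)
  for (nm in names(plist)) plist[[nm]]$val <- ck$params[[nm]]
  list(net = net, params = ck$params, params_raw = ck$params_raw,
       opt = ck$opt, ema_vox = ck$ema_vox,
       ema_plr = ck$ema_plr, iter = ck$iter, rng = ck$rng)
}

#' Predict mask and centerline for one volume
#'
#' Windows the volume, runs one forward pass, and returns (optionally
#' writes) both outputs. The centerline is the network's polyline in
#' world mm; no post-processing is applied.
#'
#' @param net a trained \linkS4class{CenterlineNet}.
#' @param vol an \linkS4class{ImageVolume} in HU.
#' @param window a \code{\link{windowSpec}}.
#' @param init_seed polyline initialization seed (fixed default makes
#'   inference deterministic).
#' @param mask_path,centerline_path optional output paths (NIfTI /
#'   VTP-or-JSON).
#' @return list(mask, centerline).
#' @export
predictCase <- function(net, vol, window = windowSpec(), init_seed = 0L,
                        mask_path = NULL, centerline_path = NULL) {
  wv <- applyWindow(vol, window)
  out <- networkForward(net, wv, init_seed = init_seed)
  if (!is.null(mask_path)) writeVolume(out$mask, mask_path)
  if (!is.null(centerline_path)) writeCenterline(out$centerline,
                                                 centerline_path)
  out
}

#' Standard artifact perturbations for robustness runs
#'
#' @param spec an \code{\link{artifactSpec}}.
#' @return named list of case-transforms (noise, calibration shift,
#'   motion blur); intensity-only, so ground truth is unchanged.
#' @export
artifactPerturbations <- function(spec = artifactSpec()) {
  list(
    noise = function(case, seed) {
      case$volume <- addGaussianNoise(case$volume, spec, seed = seed)
      case
    },
    calibration_shift = function(case, seed) {
      case$volume <- calibrationShift(case$volume, spec, seed = seed)
      case
    },
    motion_blur = function(case, seed) {
      case$volume <- motionBlur(case$volume, spec, seed = seed)
      case
    })
}

#' Geometric perturbations for robustness runs
#'
#' @param spec a \code{\link{deformationSpec}}.
#' @return named list of case-transforms (rigid, grid distortion) that
#'   transform image, mask and ground-truth centerline consistently.
#' @export
deformPerturbations <- function(spec = deformationSpec()) {
  list(
    rigid = function(case, seed)
      rigidDeform(case$volume, case$mask, case$centerline, spec,
                  seed = seed),
    grid_distortion = function(case, seed)
      gridDistortion(case$volume, case$mask, case$centerline, spec,
                     seed = seed))
}

#' Robustness experiment: metrics under input perturbations
#'
#' Evaluates the model on each case of a dataset, clean and under each
#' perturbation, and reports per-perturbation aggregate metrics plus
#' the success rate (cases where prediction and perturbation completed
#' and the predicted polyline is a valid chain).
#'
#' @param net a trained \linkS4class{CenterlineNet}.
#' @param dataset list of cases.
#' @param perturbations named list of functions \code{(case, seed) ->
#'   case}; the clean baseline row is always included.
#' @param draws independent perturbation draws per case (averaging
#'   draws tightens the per-perturbation estimate; the clean row is
#'   evaluated once per case).
#' @param window a \code{\link{windowSpec}}.
#' @param seed RNG seed for perturbation draws.
#' @param csv_path optional path for the per-perturbation CSV.
#' @return data.frame with one row per perturbation (plus
#'   \code{"clean"}): success rate and mean/sd of each metric;
#'   per-case reports attached as attribute \code{"per_case"}.
#' @export
runRobustness <- function(net, dataset,
                          perturbations = artifactPerturbations(),
                          window = windowSpec(), seed = 1L,
                          draws = 1L, csv_path = NULL) {
  set.seed(seed)
  all <- c(list(clean = function(case, seed) case), perturbations)
  rows <- list()
  per_case <- list()
  for (pname in names(all)) {
    reports <- list()
    nfail <- 0L
    ndraw <- if (pname == "clean") 1L else as.integer(draws)
    for (i in seq_along(dataset)) for (dr in seq_len(ndraw)) {
      pseed <- sample.int(1e9, 1)
      rep_i <- tryCatch({
        case <- all[[pname]](dataset[[i]], pseed)
        out <- predictCase(net, case$volume, window)
        stopifnot(nPoints(out$centerline) == net@config$num_points)
        evaluateCase(out$mask, case$mask, out$centerline,
                     case$centerline)
      }, error = function(e) NULL)
      if (is.null(rep_i)) nfail <- nfail + 1L else
        reports[[length(reports) + 1L]] <- rep_i
    }
    agg <- aggregateReports(reports)
    row <- data.frame(perturbation = pname,
                      n = length(dataset) * ndraw,
                      success_rate = 1 - nfail / (length(dataset) * ndraw))
    for (j in seq_len(nrow(agg))) {
      row[[paste0(agg$metric[j], "_mean")]] <- agg$mean[j]
      row[[paste0(agg$metric[j], "_sd")]] <- agg$sd[j]
    }
    rows[[pname]] <- row
    per_case[[pname]] <- reports
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv_path)) write.csv(out, csv_path, row.names = FALSE)
  attr(out, "per_case") <- per_case
  out
}
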