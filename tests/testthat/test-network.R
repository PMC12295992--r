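ns <- asNamespace("centrex")

test_that("encoder halves spatial dims per stage with ceiling division", {
  net <- tiny_net()
  enc <- encoderForward(net, array(runif(48^3), c(48, 48, 48)))
  dims <- t(vapply(enc, function(e) dim(e)[1:3], integer(3)))
  expect_equal(dims[, 1], c(24L, 12L, 6L, 3L, 2L))
  chs <- vapply(enc, function(e) dim(e)[4], integer(1))
  expect_equal(chs, net@config$stage_channels)
  # anisotropic input keeps per-axis ceil halving
  enc2 <- encoderForward(net, array(runif(48 * 40 * 36), c(48, 40, 36)))
  expect_equal(dim(enc2[[5]])[1:3], c(2L, 2L, 2L))
  expect_error(encoderForward(net, array(0, c(16, 16, 16))), ">= 32")
})

test_that("forward passes are deterministic given fixed weights", {
  net <- tiny_net()
  v <- array(runif(32^3), c(32, 32, 32))
  a <- voxelDecoderForward(net, v)
  b <- voxelDecoderForward(net, v)
  expect_identical(a$prob, b$prob)
  expect_identical(a$pyramid, b$pyramid)
})

test_that("voxel decoder emits an input-grid probability volume", {
  net <- tiny_net()
  v <- array(runif(36 * 32 * 40), c(36, 32, 40))
  out <- voxelDecoderForward(net, v)
  expect_equal(dim(out$prob), dim(v))
  expect_true(all(out$prob > 0 & out$prob < 1))
  expect_equal(length(out$pyramid), 5L)
})

test_that("trilinear sampling matches the 8-corner oracle", {
  set.seed(31)
  f <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
  # voxel center: exact value
  u_center <- rbind(c((2 + 0.5) / 6, (3 + 0.5) / 5, (1 + 0.5) / 4))
  expect_equal(as.numeric(sampleTrilinear(f, u_center)), f[3, 4, 2, ])
  # midpoint of two adjacent centers: arithmetic mean
  u_mid <- rbind(c((2 + 1) / 6, (3 + 0.5) / 5, (1 + 0.5) / 4))
  expect_equal(as.numeric(sampleTrilinear(f, u_mid)),
               (f[3, 4, 2, ] + f[4, 4, 2, ]) / 2)
  # outside coordinate clamps to the border value
  u_out <- rbind(c(2.0, 0.5, 0.5))
  u_edge <- rbind(c(1 - 1e-12, 0.5, 0.5))
  expect_equal(sampleTrilinear(f, u_out), sampleTrilinear(f, u_edge),
               tolerance = 1e-9)
  # random coords vs explicit weighted-corner oracle
  oracle <- function(f, u) {
    d <- dim(f)
    v <- pmin(pmax(u * d[1:3] - 0.5, 0), d[1:3] - 1)
    i0 <- pmin(floor(v), d[1:3] - 2)
    fr <- v - i0
    out <- numeric(d[4])
    for (q in 0:7) {
      dd <- c(q %% 2, (q %/% 2) %% 2, q %/% 4)
      w <- prod(ifelse(dd == 1, fr, 1 - fr))
      out <- out + w * f[i0[1] + dd[1] + 1, i0[2] + dd[2] + 1,
                         i0[3] + dd[3] + 1, ]
    }
    out
  }
  for (i in 1:25) {
    u <- runif(3)
    expect_equal(as.numeric(sampleTrilinear(f, rbind(u))), oracle(f, u),
                 tolerance = 1e-12)
  }
})

test_that("zero-initialized offset refinement is the identity on the polyline", {
  net <- createNetwork(networkConfig(stage_channels = c(2L, 3L, 4L, 5L, 6L),
                                     num_points = 9L, neighbors_k = 2L,
                                     stage1_absolute = FALSE),
                       seed = 8)
  v <- array(runif(32^3), c(32, 32, 32))
  init <- initPolyline(4, 9)
  stages <- centerlineDecoderForward(net, v, init)
  expect_length(stages, 5L)
  for (s in stages) expect_equal(s, init, tolerance = 1e-12)
})

test_that("the absolute first-stage variant reduces init dependence", {
  net <- createNetwork(networkConfig(stage_channels = c(2L, 3L, 4L, 5L, 6L),
                                     num_points = 9L, neighbors_k = 2L,
                                     stage1_absolute = TRUE),
                       seed = 8)
  v <- array(runif(32^3), c(32, 32, 32))
  s1 <- centerlineDecoderForward(net, v, initPolyline(4, 9))
  s2 <- centerlineDecoderForward(net, v, initPolyline(11, 9))
  # residual stages after an absolute stage-1: outputs nearly coincide
  # (remaining differences come only through sampled stage-1 features)
  expect_lt(max(abs(s1[[5]] - s2[[5]])), 0.05)
  # at initialization every point starts near the grid center (small
  # random head weights leave ~0.1 deviations)
  expect_lt(max(abs(s1[[1]] - 0.5)), 0.15)
})

test_that("trained coordinate heads make the polyline input-sensitive", {
  net <- createNetwork(networkConfig(stage_channels = c(2L, 3L, 4L, 5L, 6L),
                                     num_points = 9L, neighbors_k = 2L),
                       seed = 8)
  set.seed(9)
  for (p in ns$flatten_params(net@params$cld))
    if (length(dim(p$val)) == 2 && ncol(p$val) == 3)
      p$val <- p$val + matrix(rnorm(length(p$val), 0, 0.05), nrow(p$val))
  v1 <- array(runif(32^3), c(32, 32, 32))
  v2 <- array(runif(32^3), c(32, 32, 32))
  init <- initPolyline(4, 9)
  s1 <- centerlineDecoderForward(net, v1, init)[[5]]
  s2 <- centerlineDecoderForward(net, v2, init)[[5]]
  expect_gt(max(abs(s1 - s2)), 1e-8)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("neighbour offsets are tanh-bounded to one stage voxel", {
  net <- tiny_net()
  fmap <- array(rnorm(4 * 4 * 4 * 6), c(4, 4, 4, 6))
  coords <- matrix(runif(24, 0.3, 0.7), 8, 3)
  ptsf <- sampleTrilinear(fmap, coords)
  p <- net@params$cld[[1]]$nbr
  off <- tanh(ptsf %*% p$w$val + rep(p$b$val, each = 8))
  bound <- 1 / 4  # one voxel of a 4^3 stage map, normalized units
  for (j in 1:net@config$neighbors_k) {
    oj <- off[, (3 * (j - 1) + 1):(3 * j)] * bound
    expect_true(all(abs(oj) <= bound + 1e-12))
  }
  # near-zero-initialized neighbour head: neighbours start at the points
  expect_lt(max(abs(off)), 0.15)
})

test_that("rgconv blocks are residual and chain-equivariant", {
  n <- 9; cm <- 6
  Ahat <- ns$chain_adj_norm(n)
  set.seed(10)
  p <- list(gc1 = list(w = ns$ag_param(matrix(rnorm(cm * cm, 0, 0.3), cm, cm)),
                       b = ns$ag_param(rnorm(cm))),
            ln1 = list(g = ns$ag_param(rep(1, cm)), b = ns$ag_param(rep(0, cm))),
            gc2 = list(w = ns$ag_param(matrix(rnorm(cm * cm, 0, 0.3), cm, cm)),
                       b = ns$ag_param(rnorm(cm))),
            ln2 = list(g = ns$ag_param(rep(1, cm)), b = ns$ag_param(rep(0, cm))))
  X <- matrix(rnorm(n * cm), n, cm)
  out <- ns$rgconv_tape(ns$ag_const(X), p, ns$ag_const(Ahat))$val
  # zero main path -> identity
  pz <- p
  pz$gc2$w <- ns$ag_param(matrix(0, cm, cm))
  pz$gc2$b <- ns$ag_param(rep(0, cm))
  pz$ln2$g <- ns$ag_param(rep(1, cm))
  outz <- ns$rgconv_tape(ns$ag_const(X), pz, ns$ag_const(Ahat))$val
  # with gc2 zero the main path reduces to LayerNorm(0) = beta = 0
  expect_equal(outz, X, tolerance = 1e-12)
  # reversing the chain relabels symmetrically: output reverses too
  outr <- ns$rgconv_tape(ns$ag_const(X[n:1, ]), p, ns$ag_const(Ahat))$val
  expect_equal(outr, out[n:1, ], tolerance = 1e-10)
})

test_that("receptive field along the chain grows by one hop per graph conv", {
  n <- 11; cm <- 4
  Ahat <- ns$chain_adj_norm(n)
  set.seed(11)
  p <- list(gc1 = list(w = ns$ag_param(matrix(rnorm(cm * cm, 0, 0.4), cm, cm)),
                       b = ns$ag_param(rep(0, cm))),
            ln1 = list(g = ns$ag_param(rep(1, cm)), b = ns$ag_param(rep(0, cm))),
            gc2 = list(w = ns$ag_param(matrix(rnorm(cm * cm, 0, 0.4), cm, cm)),
                       b = ns$ag_param(rep(0, cm))),
            ln2 = list(g = ns$ag_param(rep(1, cm)), b = ns$ag_param(rep(0, cm))))
  X <- ns$ag_param(matrix(rnorm(n * cm), n, cm))
  out <- ns$rgconv_tape(X, p, ns$ag_const(Ahat))
  # gradient of an interior point's output w.r.t. the input is confined
  # to 2 hops (one block = two graph convs); LayerNorm mixes only within
  # a point, so sparsity is preserved
  # probe a single output entry (a whole-row probe lies in LayerNorm's
  # shift-invariant null space and would show no propagation)
  mask <- matrix(0, n, cm); mask[6, 1] <- 1
  ns$ag_backward(ns$ag_sum(ns$ag_mul(out, ns$ag_const(mask))))
  touched <- which(rowSums(abs(X$grad)) > 1e-12)
  expect_true(all(touched >= 4 & touched <= 8))
  expect_true(all(c(5, 6, 7) %in% touched))
})

test_that("the full forward contract holds for both heads", {
  net <- tiny_net()
  cs <- tiny_case()
  wv <- applyWindow(cs$volume)
  out <- networkForward(net, wv)
  expect_equal(gridDim(out$mask), gridDim(cs$volume))
  expect_equal(nPoints(out$centerline), net@config$num_points)
  expect_length(out$stages, 5L)
  # full-scale preset emits 96 points
  expect_equal(netPresetPaper()$num_points, 96L)
  cfg96 <- networkConfig(stage_channels = c(2L, 2L, 3L, 3L, 4L),
                         num_points = 96L)
  out96 <- networkForward(createNetwork(cfg96, seed = 1), wv)
  expect_equal(nPoints(out96$centerline), 96L)
})

test_that("random polyline initialization is seeded and uniform", {
  p1 <- initPolyline(7, 32)
  p2 <- initPolyline(7, 32)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  gaps <- sqrt(rowSums(diff(p1)^2))
  expect_lt(max(gaps) - min(gaps), 1e-9)
  pu <- initPolyline(7, 32, mode = "uniform")
  expect_true(all(pu >= 0.2 & pu <= 0.8))
})

test_that("tiny-preset inference fits an interactive CPU budget", {
  net <- createNetwork(netPresetTiny(), seed = 1)
  cs <- tiny_case()
  t0 <- proc.time()
  out <- predictCase(net, cs$volume)
  expect_lt((proc.time() - t0)[["elapsed"]], 5)
  expect_equal(nPoints(out$centerline), 32L)
})

test_that("end-to-end gradients stay finite on a random phantom", {
  net <- tiny_net()
  cs <- tiny_case()
  varr <- volValues(applyWindow(cs$volume))[1:32, 1:32, 1:32]
  fw <- ns$forward_tape(net, varr, initPolyline(3, 8))
  mt <- volValues(cs$mask)[1:32, 1:32, 1:32]
  ct <- matrix(runif(12, 0.3, 0.7), 4, 3)
  l <- ns$ag_add(
    ns$ag_add(ns$tape_voxel_loss(fw$prob, mt),
              Reduce(ns$ag_add, lapply(fw$stages, ns$tape_chamfer, ct = ct))),
    ns$ag_add(ns$tape_edge_reg(fw$stages[[5]]),
              ns$tape_plr(fw$stages[[5]], fw$prob)))
  ns$ag_backward(l)
  for (p in ns$flatten_params(net@params)) {
    expect_false(is.null(p$grad))
    expect_true(all(is.finite(p$grad)))
  }
})
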