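ns <- asNamespace("centrex")

test_that("voxel loss reproduces hand-evaluated values", {
  # single voxel, Mt = 1, Mp = 0.5: -0.5*ln(0.5) - 2*0.5/1.5
  one <- array(1, c(1, 1, 1))
  half <- array(0.5, c(1, 1, 1))
  expect_equal(voxelLoss(half, one), -0.5 * log(0.5) - 2 * 0.5 / 1.5,
               tolerance = 1e-12)
  expect_equal(voxelLoss(half, one), -0.32009, tolerance = 1e-4)
  # perfect binary prediction tends to -1
  mt <- array(as.double(runif(4^3) > 0.5), c(4, 4, 4))
  expect_equal(voxelLoss(mt, mt), -1, tolerance = 1e-6)
  # empty ground truth gives 0
  expect_equal(voxelLoss(array(runif(64, 0.1, 0.9), c(4, 4, 4)),
                         array(0, c(4, 4, 4))), 0)
})

test_that("Chamfer distance matches the toy cases and the brute force", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(chamferLoss(A, A), 0)
  expect_equal(chamferLoss(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 10)
  expect_equal(chamferLoss(rbind(c(0, 0, 0), c(2, 0, 0)),
                           rbind(c(1, 0, 0))), 3)
  set.seed(11)
  for (i in 1:200) {
    P <- matrix(runif(3 * sample(2:30, 1), -10, 10), ncol = 3)
    T <- matrix(runif(3 * sample(2:30, 1), -10, 10), ncol = 3)
    expect_equal(chamferLoss(P, T), oracle_chamfer(P, T),
                 tolerance = 1e-9)
    expect_equal(chamferLoss(P, T, squared = TRUE),
                 oracle_chamfer(P, T, squared = TRUE), tolerance = 1e-9)
  }
})

test_that("Chamfer is permutation-invariant and zero iff equal sets", {
  set.seed(12)
  P <- matrix(runif(30), 10, 3)
  expect_equal(chamferLoss(P[sample(10), ], P[sample(10), ]), 0,
               tolerance = 1e-12)
  Q <- P; Q[4, 1] <- Q[4, 1] + 0.5
  expect_gt(chamferLoss(P, Q), 0)
  expect_equal(chamferLoss(P, Q), chamferLoss(Q, P))
})

test_that("edge regularizer favors uniform spacing for fixed endpoints", {
  expect_equal(edgeLengthReg(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2)
  expect_equal(edgeLengthReg(rbind(c(0, 0, 0), c(3, 4, 0))), 25)
  expect_equal(edgeLengthReg(rbind(c(0, 0, 0), c(0.5, 0, 0), c(2, 0, 0))),
               0.25 + 2.25)
  # uniform placement is the argmin over random interior perturbations
  set.seed(13)
  for (n in 3:6) {
    uni <- cbind(seq(0, 2, length.out = n), 0, 0)
    base <- edgeLengthReg(uni)
    for (r in 1:40) {
      pert <- uni
      pert[2:(n - 1), ] <- pert[2:(n - 1), , drop = FALSE] +
        matrix(runif(3 * (n - 2), -0.3, 0.3), ncol = 3)
      expect_gte(edgeLengthReg(pert), base)
    }
  }
})

test_that("point-lumen penalty matches its closed forms", {
  m1 <- array(1, c(4, 4, 4))
  pts <- matrix(0.5, 5, 3)
  expect_equal(pointLumenReg(pts, m1), -1, tolerance = 1e-6)
  mh <- array(0.5, c(4, 4, 4))
  n <- 5
  expect_equal(pointLumenReg(pts, mh),
               n * (-0.5 * log(0.5)) - 2 * (0.5 * n) / (1.5 * n),
               tolerance = 1e-9)
})

test_that("lumen penalty gradients respect the stop-gradient contract", {
  set.seed(14)
  mp <- ns$ag_param(array(runif(5^3, 0.2, 0.8), c(5, 5, 5)))
  co <- ns$ag_param(matrix(runif(9, 0.3, 0.7), 3, 3))
  ns$ag_backward(ns$tape_plr(co, mp))
  expect_null(mp$grad)           # no gradient into the voxel head
  expect_gt(max(abs(co$grad)), 0)  # but coordinates receive gradient
})

test_that("EMA follows the closed-form geometric series", {
  st <- emaInit(alpha = 0.9, init = 0)
  for (k in 1:25) {
    st <- emaUpdate(st, 1)
    expect_equal(st$value, 1 - 0.9^k, tolerance = 1e-12)
  }
  # constant stream converges to the constant
  st <- emaInit(0.9, init = 5)
  for (k in 1:400) st <- emaUpdate(st, 2)
  expect_equal(st$value, 2, tolerance = 1e-12)
  # alpha = 0 tracks the latest value exactly
  st <- emaInit(0)
  st <- emaUpdate(st, 7)
  expect_equal(st$value, 7)
})

test_that("total loss composes its terms and books them consistently", {
  set.seed(15)
  mt <- array(as.double(runif(4^3) > 0.6), c(4, 4, 4))
  mp <- array(runif(4^3, 0.05, 0.95), c(4, 4, 4))
  stages <- lapply(1:5, function(s) matrix(runif(12, 0.2, 0.8), 4, 3))
  ct <- matrix(runif(9, 0.2, 0.8), 3, 3)
  ev <- emaInit(); ep <- emaInit()
  r <- totalLoss(mp, mt, stages, ct, ev, ep)
  br <- r$breakdown
  expect_equal(br$l_total, br$l_vox + br$l_cd + br$l_elr + br$l_plr,
               tolerance = 1e-9)
  expect_equal(br$l_cd,
               sum(vapply(stages, chamferLoss, numeric(1), ct = ct)))
  expect_equal(br$l_elr, edgeLengthReg(stages[[5]]))
  expect_equal(br$l_vox, 0.1 * voxelLoss(mp, mt))  # first EMA update
  expect_equal(r$ema_vox$step, 1L)
})

test_that("centerline losses send no gradient to the mask head", {
  net <- tiny_net()
  varr <- array(runif(32^3), c(32, 32, 32))
  fw <- ns$forward_tape(net, varr, initPolyline(2, 8))
  ct <- matrix(runif(12, 0.3, 0.7), 4, 3)
  l <- ns$ag_add(ns$ag_add(
    Reduce(ns$ag_add, lapply(fw$stages, ns$tape_chamfer, ct = ct)),
    ns$tape_edge_reg(fw$stages[[5]])),
    ns$tape_plr(fw$stages[[5]], fw$prob))
  ns$ag_backward(l)
  hw <- ns$flatten_params(net@params)[["head.w"]]
  expect_true(is.null(hw$grad) || max(abs(hw$grad)) == 0)
})

test_that("the composite loss decreases when overfitting one phantom", {
  set.seed(16)
  ds <- makePhantomDataset(1, phantomDistributionTiny(), seed = 9)
  net <- createNetwork(networkConfig(stage_channels = c(4L, 6L, 8L, 10L, 12L),
                                     num_points = 12L, neighbors_k = 2L),
                       seed = 2)
  res <- trainNetwork(net, ds,
                      trainConfig(epochs = 1L, iterations_per_epoch = 50L,
                                  batch_size = 1L, seed = 4, augment = 0))
  expect_lt(mean(tail(res$log$l_total, 5)), mean(head(res$log$l_total, 5)))
  expect_true(all(is.finite(res$log$l_total)))
})
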