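test_that("volumetric dice counts overlap in percent", {
  a <- array(0, c(10, 10, 10)); a[1:5, , ] <- 1
  expect_equal(volumetricDice(a, a), 100)
  b <- array(0, c(10, 10, 10)); b[6:10, , ] <- 1
  expect_equal(volumetricDice(a, b), 0)
  # |A| = |B| = 100, overlap 50
  a2 <- array(0, c(10, 10, 10)); a2[1:100] <- 1
  b2 <- array(0, c(10, 10, 10)); b2[51:150] <- 1
  expect_equal(volumetricDice(a2, b2), 50)
  expect_equal(volumetricDice(a * 0, b * 0), 100)  # both-empty convention
})

test_that("polyline resampling is endpoint-anchored and length-preserving", {
  seg <- rbind(c(0, 0, 0), c(10, 0, 0))
  r <- resamplePolyline(seg, 1)
  expect_equal(nrow(r), 11L)
  expect_equal(r[, 1], 0:10)
  # total length preserved within one step
  set.seed(21)
  p <- rand_polyline(8)
  L <- polylineLength(Centerline(p))
  r2 <- resamplePolyline(p, 2)
  expect_lt(abs(sum(sqrt(rowSums(diff(r2)^2))) - L), 2)
  # halving an exactly dividing step nests the sample points
  ra <- resamplePolyline(seg, 2)
  rb <- resamplePolyline(seg, 1)
  expect_true(all(ra[, 1] %in% rb[, 1]))
})

test_that("surface dice separates the parallel-offset tolerance cases", {
  a <- rbind(c(0, 0, 0), c(100, 0, 0))
  b <- rbind(c(0, 2, 0), c(100, 2, 0))
  expect_equal(surfaceDice1d(a, a, 1), 100)
  expect_equal(surfaceDice1d(a, b, 3), 100)
  expect_equal(surfaceDice1d(a, b, 1), 0)
  expect_equal(hd95(a, b), 2, tolerance = 1e-9)
  expect_equal(assd(a, b), 2, tolerance = 1e-9)
  expect_equal(hd95(a, a), 0)
  expect_equal(assd(a, a), 0)
})

test_that("distances agree with the all-pairs point-to-segment oracle", {
  set.seed(22)
  for (i in 1:100) {
    P <- rand_polyline(sample(3:10, 1))
    Q <- rand_polyline(sample(3:10, 1))
    pts <- matrix(runif(15, -10, 60), 5, 3)
    expect_equal(pointPolylineDist(pts, Q), oracle_point_polyline(pts, Q),
                 tolerance = 1e-9)
    expect_lte(surfaceDice1d(P, Q, 1), surfaceDice1d(P, Q, 3))
    expect_lte(assd(P, Q), hd95(P, Q) + 1e-9)
  }
})

test_that("surface dice is monotone in tolerance", {
  set.seed(23)
  for (i in 1:100) {
    P <- rand_polyline(6); Q <- rand_polyline(6)
    taus <- c(0.5, 1, 2, 3, 5, 8)
    sds <- vapply(taus, function(t) surfaceDice1d(P, Q, t), numeric(1))
    expect_true(all(diff(sds) >= 0))
  }
})

test_that("centerline metrics are invariant under joint rigid motions", {
  set.seed(24)
  P <- rand_polyline(7); Q <- rand_polyline(6)
  R <- centrex:::rotmat3(c(21, -40, 65))
  tr <- c(12, -8, 30)
  Pr <- t(R %*% t(P)) + rep(tr, each = nrow(P))
  Qr <- t(R %*% t(Q)) + rep(tr, each = nrow(Q))
  expect_equal(surfaceDice1d(P, Q, 3), surfaceDice1d(Pr, Qr, 3),
               tolerance = 1e-6)
  expect_equal(hd95(P, Q), hd95(Pr, Qr), tolerance = 1e-6)
  expect_equal(assd(P, Q), assd(Pr, Qr), tolerance = 1e-6)
})

test_that("mass-centroid baseline recovers a straight axis and fails on arcs", {
  cs <- straight_case()
  cm <- massCentroidBaseline(cs$mask)
  ax <- clPoints(cs$centerline)[1, 1:2]
  pts <- clPoints(cm)
  # drop end slices where the tube cap clips the disc
  interior <- pts[-c(1, nrow(pts)), ]
  expect_lt(max(abs(sweep(interior[, 1:2], 2, ax))), 0.5 * 2)
  sd_straight <- surfaceDice1d(cm, cs$centerline, 3)
  # non-axis-aligned arc: the per-slice centroid drifts off the curve
  spa <- phantomSpec(curve_kind = "arc", arc_radius_mm = 50,
                     arc_angle_deg = 170, radius_mm = 9,
                     edge_softness_mm = 0, grid_shape = c(96, 96, 96),
                     rotation_deg = c(90, 0, 0))
  arc <- makePhantom(spa)
  cma <- suppressWarnings(massCentroidBaseline(arc$mask))
  sd_arc <- surfaceDice1d(cma, arc$centerline, 3)
  expect_lt(sd_arc, sd_straight)
  expect_error(massCentroidBaseline(
    ProbabilityMask(array(0, c(8, 8, 8)))), "empty")
})

test_that("mass-centroid baseline flags disconnected slice foreground", {
  m <- array(0, c(12, 12, 6))
  m[2:4, 2:4, ] <- 1
  m[8:10, 8:10, ] <- 1
  expect_warning(cm <- massCentroidBaseline(ProbabilityMask(m)),
                 "disconnected")
  expect_equal(length(attr(cm, "disconnected_slices")), 6L)
})

test_that("case evaluation bundles and aggregates the five metrics", {
  cs <- tiny_case()
  rep <- evaluateCase(cs$mask, cs$mask, cs$centerline, cs$centerline)
  expect_equal(unname(unlist(rep)), c(100, 100, 100, 0, 0))
  # fields match individually computed metrics on an imperfect pair
  other <- Centerline(clPoints(cs$centerline) +
                        rep(c(1.5, 0, 0), each = nPoints(cs$centerline)))
  r2 <- evaluateCase(cs$mask, cs$mask, other, cs$centerline)
  expect_equal(r2$sd1_pct, surfaceDice1d(other, cs$centerline, 1))
  expect_equal(r2$hd95_mm, hd95(other, cs$centerline))
  agg <- aggregateReports(list(rep, r2))
  expect_equal(agg$mean[agg$metric == "hd95_mm"], mean(c(0, r2$hd95_mm)))
  expect_equal(agg$sd[agg$metric == "assd_mm"],
               sqrt(mean((c(0, r2$assd_mm) - mean(c(0, r2$assd_mm)))^2)))
})
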