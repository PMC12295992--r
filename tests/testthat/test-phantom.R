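test_that("straight tube curve has exact arclength sampling", {
  sp <- phantomSpec(curve_kind = "straight", radius_mm = 10,
                    length_mm = 120, grid_shape = c(96, 96, 96))
  cl <- generateCurve(sp)
  p <- clPoints(cl)
  expect_equal(nrow(p), 21L)
  gaps <- sqrt(rowSums(diff(p)^2))
  expect_equal(gaps, rep(6, 20), tolerance = 1e-12)
  # collinear: centered points have rank 1
  expect_equal(qr(scale(p, scale = FALSE))$rank, 1L)
})

test_that("arc polyline length converges to R*theta", {
  sp <- phantomSpec(curve_kind = "arc", arc_radius_mm = 60,
                    arc_angle_deg = 120, gt_point_spacing_mm = 0.25,
                    radius_mm = 8, grid_shape = c(96, 96, 96))
  cl <- generateCurve(sp)
  expect_equal(polylineLength(cl), 60 * 120 * pi / 180, tolerance = 3e-3)
})

test_that("default aorta-like spec matches the annotation density regime", {
  cl <- generateCurve(phantomSpec())
  expect_gte(nPoints(cl), 20L)
  expect_lte(nPoints(cl), 45L)
})

test_that("curves that do not fit the grid are rejected loudly", {
  sp <- phantomSpec(curve_kind = "straight", length_mm = 400,
                    radius_mm = 10, grid_shape = c(96, 96, 96))
  expect_error(generateCurve(sp), "does not fit")
})

test_that("rasterized straight tube matches the analytic cylinder", {
  cs <- straight_case()
  m <- volValues(cs$mask)
  sp <- cs$spec
  vol <- sum(m) * prod(sp$spacing_mm)
  expect_lt(abs(vol / (pi * 8^2 * 160) - 1), 0.10)
  # per-slice centroid within 0.5 voxel of the analytic axis
  counts <- apply(m, 3, sum)
  interior <- which(counts == max(counts))
  axis_xy <- clPoints(cs$centerline)[1, 1:2]
  for (k in interior[c(1, length(interior) %/% 2, length(interior))]) {
    ij <- which(m[, , k] > 0, arr.ind = TRUE)
    cen <- (colMeans(ij) - 1 + 0.5) * sp$spacing_mm[1:2]
    expect_lt(max(abs(cen - axis_xy)), 0.5 * sp$spacing_mm[1])
  }
})

test_that("rasterization is monotone in radius and stable under refinement", {
  sp <- straight_spec()
  cl <- generateCurve(sp)
  m1 <- volValues(rasterizeTube(cl, sp, radius_mm = 8))
  m2 <- volValues(rasterizeTube(cl, sp, radius_mm = 12))
  expect_true(all(m2[m1 > 0] == 1))
  # halving the dense resampling step changes no voxel label
  mh <- volValues(rasterizeTube(cl, sp, dense_step_mm = 0.25))
  expect_identical(m1, mh)
})

test_that("sub-voxel radius exercises the empty-mask warning path", {
  sp <- straight_spec()
  cl <- generateCurve(sp)
  expect_warning(rasterizeTube(cl, sp, radius_mm = 0.4), "empty")
})

test_that("ground-truth points lie deep inside the mask", {
  cs <- straight_case()
  u <- worldToNormalized(clPoints(cs$centerline), cs$mask)
  vals <- sampleTrilinear(volValues(cs$mask), u)
  expect_true(all(vals == 1))
  dist <- attr(cs$mask, "dist_mm")
  dv <- sampleTrilinear(array(dist, c(dim(dist), 1)), u)
  expect_true(all(dv < cs$spec$radius_mm / 2))
})

test_that("rendering is a two-level image blurred by edge softness", {
  cs <- straight_case()
  v0 <- renderVolume(cs$mask, cs$spec)   # softness 0
  expect_setequal(unique(as.numeric(volValues(v0))), c(0, 300))
  expect_equal(mean(volValues(v0) == 300), mean(volValues(cs$mask)))
  sp1 <- straight_spec(); sp1$edge_softness_mm <- 1
  v1 <- volValues(renderVolume(cs$mask, sp1))
  # eroded lumen (strictly interior voxels) keeps the lumen intensity
  dist <- attr(cs$mask, "dist_mm")
  interior <- dist <= cs$spec$radius_mm - 2 * max(sp1$spacing_mm)
  expect_lt(abs(mean(v1[interior]) - 300), 1)
})

test_that("phantom datasets are reproducible and well-formed", {
  d1 <- makePhantomDataset(2, phantomDistributionTiny(), seed = 5)
  d2 <- makePhantomDataset(2, phantomDistributionTiny(), seed = 5)
  expect_identical(volValues(d1[[1]]$volume), volValues(d2[[1]]$volume))
  expect_identical(volValues(d1[[2]]$mask), volValues(d2[[2]]$mask))
  for (cs in d1) {
    expect_s4_class(cs$volume, "ImageVolume")
    expect_s4_class(cs$mask, "ProbabilityMask")
    expect_s4_class(cs$centerline, "Centerline")
    expect_true(validObject(cs$centerline))
  }
  expect_equal(nrow(attr(d1, "manifest")), 2L)
})

test_that("annotation counts under the default distribution stay aortic", {
  dist <- phantomDistribution()
  set.seed(31)
  seeds <- sample.int(1e6, 100)
  counts <- vapply(seeds, function(s)
    nPoints(generateCurve(centrex:::draw_spec(dist, s))), numeric(1))
  expect_gt(mean(counts), 20)
  expect_lt(mean(counts), 45)
})

test_that("dataset export writes standard formats with a manifest", {
  dir <- file.path(tempdir(), "cx_ds")
  makePhantomDataset(1, phantomDistributionTiny(), seed = 3, dir = dir)
  expect_true(file.exists(file.path(dir, "vol_001.nii.gz")))
  expect_true(file.exists(file.path(dir, "mask_001.nii.gz")))
  expect_true(file.exists(file.path(dir, "cl_001.vtp")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(man$n_gt_points,
               nPoints(readCenterline(file.path(dir, "cl_001.vtp"))))
  unlink(dir, recursive = TRUE)
})
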