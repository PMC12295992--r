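test_that("additive noise has the configured mean and variance", {
  v <- ImageVolume(array(100, c(64, 64, 64)))
  out <- addGaussianNoise(v, artifactSpec(), seed = 41)
  d <- volValues(out) - volValues(v)
  expect_lt(abs(mean(d)), 0.1)
  expect_lt(abs(mean((d - mean(d))^2) - 15), 1)
  # zero variance is the identity
  z <- addGaussianNoise(v, artifactSpec(noise_variance_hu2 = 0))
  expect_identical(volValues(z), volValues(v))
})

test_that("calibration shift is one bounded scalar per volume", {
  v <- ImageVolume(array(rnorm(8^3, 0, 100), c(8, 8, 8)))
  out <- calibrationShift(v, seed = 42)
  d <- volValues(out) - volValues(v)
  expect_equal(max(d) - min(d), 0)
  set.seed(43)
  shifts <- replicate(1000, attr(calibrationShift(v), "shift_hu"))
  expect_true(all(shifts >= -10 & shifts <= 10))
  expect_gt(max(abs(shifts)), 8)  # actually spans the range
  # windowed output shifts by c/1400 at interior intensities
  c0 <- attr(out, "shift_hu")
  vi <- ImageVolume(array(150, c(4, 4, 4)))
  w0 <- volValues(applyWindow(vi))
  w1 <- volValues(applyWindow(ImageVolume(volValues(vi) + c0)))
  expect_equal(w1 - w0, array(c0 / 1400, c(4, 4, 4)), tolerance = 1e-12)
})

test_that("motion blur preserves total intensity and has line support", {
  set.seed(44)
  v <- ImageVolume(array(runif(32^3, 0, 300), c(32, 32, 32)))
  for (amp in 1:3) {
    out <- motionBlur(v, artifactSpec(motion_direction = c(1, 0, 0)),
                      amplitude = amp)
    expect_lt(abs(sum(volValues(out)) / sum(volValues(v)) - 1), 1e-6)
  }
  expect_identical(volValues(motionBlur(v, amplitude = 0)), volValues(v))
  # impulse spreads to exactly the kernel support along the direction
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  out <- motionBlur(ImageVolume(imp),
                    artifactSpec(motion_direction = c(0, 0, 1)),
                    amplitude = 2)
  nz <- which(volValues(out) > 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] == 8 & nz[, 2] == 8))
  expect_equal(sort(nz[, 3]), 7:9)  # length amp+1 = 3 kernel
})

test_that("rigid deformation transforms all case members consistently", {
  cs <- tiny_case()
  idt <- rigidDeform(cs$volume, cs$mask, cs$centerline,
                     scale = 1, rotation_deg = c(0, 0, 0))
  expect_identical(volValues(idt$volume), volValues(cs$volume))
  expect_identical(clPoints(idt$centerline), clPoints(cs$centerline))
  # rotate forth and back: centerline recovered exactly (analytic map)
  r1 <- rigidDeform(cs$volume, cs$mask, cs$centerline,
                    scale = 1, rotation_deg = c(0, 0, 8))
  r2 <- rigidDeform(r1$volume, r1$mask, r1$centerline,
                    scale = 1, rotation_deg = c(0, 0, -8))
  expect_lt(max(abs(clPoints(r2$centerline) - clPoints(cs$centerline))),
            1e-6)
  # image recovered within interpolation tolerance (interior voxels)
  inner <- 9:40
  err <- abs(volValues(r2$volume) - volValues(cs$volume))[inner, inner, inner]
  expect_lt(mean(err), 6)
  # transformed GT still inside the transformed mask
  vals <- sampleTrilinear(volValues(r1$mask),
                          worldToNormalized(clPoints(r1$centerline), r1$mask))
  expect_gt(mean(vals > 0.5), 0.95)
})

test_that("excessive rigid transforms are rejected", {
  cs <- tiny_case()
  expect_error(rigidDeform(cs$volume, cs$mask, cs$centerline,
                           scale = 2.5, rotation_deg = c(0, 0, 0)),
               "out of the grid")
})

test_that("grid distortion moves the centerline by the sampled field", {
  cs <- tiny_case()
  spec <- deformationSpec(max_disp_mm = 3)
  idt <- gridDistortion(cs$volume, cs$mask, cs$centerline,
                        deformationSpec(max_disp_mm = 0), seed = 45)
  expect_identical(volValues(idt$volume), volValues(cs$volume))
  out <- gridDistortion(cs$volume, cs$mask, cs$centerline, spec, seed = 46)
  set.seed(46)
  u <- centrex:::make_disp_field(spec, gridDim(cs$volume),
                                 spacingMm(cs$volume))
  un <- worldToNormalized(clPoints(cs$centerline), cs$volume)
  expect_equal(clPoints(out$centerline),
               clPoints(cs$centerline) + sampleTrilinear(u, un),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("default distortion magnitudes keep the field invertible", {
  cs <- tiny_case()
  spec <- deformationSpec()
  set.seed(47)
  seeds <- sample.int(1e6, 100)
  jmins <- vapply(seeds, function(s) {
    set.seed(s)
    u <- centrex:::make_disp_field(spec, gridDim(cs$volume),
                                   spacingMm(cs$volume))
    for (a in 1:3) u[, , , a] <- u[, , , a] / spacingMm(cs$volume)[a]
    centrex:::field_jacobian_ok(u)
  }, numeric(1))
  expect_true(all(jmins > 0))
})

test_that("training augmentation composes reproducibly and keeps containment", {
  cs <- tiny_case()
  a1 <- trainingAugment(cs, seed = 48)
  a2 <- trainingAugment(cs, seed = 48)
  expect_identical(volValues(a1$volume), volValues(a2$volume))
  expect_identical(clPoints(a1$centerline), clPoints(a2$centerline))
  # double flip is the identity
  f2 <- centrex:::flip_case(centrex:::flip_case(cs, 1), 1)
  expect_identical(volValues(f2$volume), volValues(cs$volume))
  expect_equal(clPoints(f2$centerline), clPoints(cs$centerline),
               tolerance = 1e-12)
  # the GT centerline stays inside the mask (1-voxel tolerance) across seeds
  for (s in 1:30) {
    aug <- trainingAugment(cs, seed = 100 + s)
    m <- volValues(aug$mask)
    sm <- centrex:::.cx_gaussian_blur(m, dim(m), c(1, 1, 1))  # 1-voxel halo
    vals <- sampleTrilinear(sm, worldToNormalized(clPoints(aug$centerline),
                                                  aug$mask))
    expect_gt(mean(vals > 0.05), 0.97)
  }
})

test_that("intensity-only artifacts leave ground truth metrics perfect", {
  cs <- tiny_case()
  spec <- artifactSpec()
  for (f in artifactPerturbations(spec)) {
    p <- f(cs, seed = 49)
    expect_identical(clPoints(p$centerline), clPoints(cs$centerline))
    expect_equal(surfaceDice1d(p$centerline, cs$centerline, 1), 100)
    expect_identical(volValues(p$mask), volValues(cs$mask))
  }
})
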