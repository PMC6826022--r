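test_that("segmentation recovers analytic shapes and rejects degenerate input", {
  frame <- discFrame(c(128L, 128L), list(c(64, 64)), 50)
  mask <- segmentVentricle(frame)
  expect_lt(abs(sum(mask) - pi * 50^2) / (pi * 50^2), 0.01)

  expect_error(segmentVentricle(matrix(0.5, 64, 64)),
               class = "segmentationFailureError")

  # two components: only the larger is retained
  two <- discFrame(c(128L, 128L), list(c(40, 40), c(100, 100)),
                   c(18, 5.5))  # areas ~1018 and ~95 px
  mask2 <- segmentVentricle(two)
  expect_lt(abs(sum(mask2) - pi * 18^2) / (pi * 18^2), 0.05)
  expect_false(any(mask2[90:110, 90:110]))
})

test_that("frame geometry measures a disk correctly", {
  frame <- discFrame(c(128L, 128L), list(c(64, 64)), 50)
  g <- frameGeometry(segmentVentricle(frame), pixel_size = 1, n_rays = 36)
  expect_lt(sd(g$radii) / mean(g$radii), 0.02)       # circular symmetry
  expect_lt(abs(g$long_length - 100), 2)             # diameter
  expect_equal(g$centroid, c(row = 64, col = 64), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_error(frameGeometry(matrix(FALSE, 10, 10), 1),
               class = "emptyMaskError")
})

test_that("biplane area-length volume follows the printed formula", {
  expect_equal(biplaneVolume(3, 2), 4)
  expect_equal(biplaneVolume(0, 5), 0)
  # exact on the ellipsoid a = b = 1, c = 1.5: A = pi, L = 3
  expect_equal(biplaneVolume(pi, 3), 4 / 3 * pi * 1 * 1 * 1.5)
  expect_error(biplaneVolume(-1, 2), class = "negativeInputError")
})

test_that("cycle detection finds one ED and ES per pacing period", {
  t <- (0:197) / 66
  vol <- 2 + (1 + cos(2 * pi * 2 * t))        # 2 Hz raised cosine, 3 s
  cyc <- detectCycles(vol, frame_rate = 66, pacing_rate = 2)
  expect_equal(nrow(cyc), 6)
  expect_error(detectCycles(rep(3, 198), 66, 2),
               class = "cycleDetectionError")
  # simulator round trip: detected EDs match ground-truth EDs within 1 frame
  sim <- noiselessVideoSim()
  cyc2 <- detectCycles(sim$truth$frames$volume, 66, 2)
  expect_true(all(abs(cyc2$ed_frame - sim$truth$ed_frames) <= 1))
  expect_true(all(abs(cyc2$es_frame - sim$truth$es_frames) <= 1))
})

test_that("cycle indices implement EF, FS and FAC", {
  expect_equal(cycleIndices(4, 2)$ef, 0.5)
  expect_equal(cycleIndices(4, 2, l_d = 2, l_s = 1.5)$fs, 0.25)
  expect_equal(cycleIndices(4, 2, eda = 4, esa = 3)$fac, 0.25)
  expect_equal(cycleIndices(4, 4)$ef, 0)
  expect_error(cycleIndices(0, 0), class = "divisionByZeroError")
  expect_error(cycleIndices(2, 4), class = "invalidParameterError")
})

test_that("strain-rate extrema match the analytic derivative", {
  fr <- 660
  t <- seq(0, 1, by = 1 / fr)
  strain <- -0.1 * (1 - cos(2 * pi * 2 * t)) / 2
  radii <- 10 * (1 + strain)               # mean radius encoding the strain
  sv <- strainVelocitySeries(radii, fr, window = 7)
  expect_equal(max(abs(sv$velocity)), 0.1 * pi * 2, tolerance = 0.02)
  # contraction velocity is the negative extremum
  expect_lt(sv$max_contraction_velocity, 0)
  # smoothing off on noiseless data changes the extrema by < 2%
  sv1 <- strainVelocitySeries(radii, fr, window = 1)
  expect_equal(sv1$max_contraction_velocity, sv$max_contraction_velocity,
               tolerance = 0.02)
  # static input
  sv0 <- strainVelocitySeries(rep(10, 50), fr)
  expect_true(all(sv0$strain == 0) && all(sv0$velocity == 0))
  expect_error(strainVelocitySeries(c(1, 2, 3), fr),
               class = "insufficientFramesError")
})

test_that("velocity-strain loop area matches the parametric ellipse", {
  w <- 4 * pi
  t <- seq(0, 0.5, length.out = 2000)
  s <- 0.1 * sin(w * t)
  v <- 0.1 * w * cos(w * t)
  expect_equal(velocityStrainLoop(s, v), pi * w * 0.1^2, tolerance = 0.01)
  # orientation symmetry
  expect_equal(velocityStrainLoop(rev(s), rev(v)),
               velocityStrainLoop(s, v))
  # degenerate loop
  expect_equal(velocityStrainLoop(rep(0, 10), rep(0, 10)), 0)
  expect_error(velocityStrainLoop(c(0, 0.5, 1), c(0, 1, 0)),
               class = "openLoopError")
})

test_that("full-chain analysis recovers simulator ground truth", {
  sim <- noiselessVideoSim()
  hs <- noiselessHeartSummary()
  m <- cycleMeans(hs)
  expect_equal(m[["ef"]], sim$truth$ef, tolerance = 0.02)
  expect_equal(m[["fs"]], sim$truth$fs, tolerance = 0.03)
  expect_equal(m[["fac"]], sim$truth$fac, tolerance = 0.03)
  expect_gte(nrow(cycleTable(hs)), 3)
  # all cycles identical by construction: means equal any single cycle
  expect_equal(cycleTable(hs)$ef[1], m[["ef"]], tolerance = 1e-9)
  # means are the arithmetic means of the per-cycle values
  expect_equal(unname(m[["edv"]]), mean(cycleTable(hs)$edv))
})

test_that("EF, FS, FAC are invariant to uniform intensity rescaling", {
  sim <- noiselessVideoSim()
  dimmed <- BiplaneVideo(planeLong(sim$video) * 0.4,
                         planeShort(sim$video) * 0.4,
                         pixelSize(sim$video), frameRate(sim$video))
  m0 <- cycleMeans(noiselessHeartSummary())
  m1 <- cycleMeans(summarizeHeart(dimmed))
  expect_equal(m1[c("ef", "fs", "fac")], m0[c("ef", "fs", "fac")],
               tolerance = 1e-9)
})

test_that("segmentation + geometry recover per-frame truth within 1%", {
  sim <- noiselessVideoSim()
  ps <- pixelSize(sim$video)
  for (k in c(1L, 9L, 17L)) {   # ED, mid, ES of the first cycle
    gs <- frameGeometry(segmentVentricle(planeShort(sim$video)[, , k]), ps)
    expect_equal(gs$area, sim$truth$frames$short_area_mm2[k],
                 tolerance = 0.01)
  }
})
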