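test_that("every generator is a pure function of (params, seed)", {
  gens <- list(
    video = function() simBeatingHeartVideo(
      cardiacSimParams(duration = 1.5, frame_rate = 30, heart_rate = 2,
                       image_shape = c(64L, 64L), pixel_size = 0.06,
                       noise_sd = 0.05, seed = 7)),
    trace = function() simMyofibrilTrace(
      myofibrilSimParams(noise_sd = 0.02, seed = 7)),
    doppler = function() simDopplerWaveform(
      dopplerSimParams(noise_sd = 1, seed = 7)),
    swim = function() simSwimCohort(seed = 7),
    surv = function() simSurvivalCohort(seed = 7),
    fraction = function() simAreaFractionImage(fraction = 0.3, seed = 7),
    nuclei = function() simNucleiImage(n = 20, k = 5, seed = 7),
    pca = function() simForcePca(noise_sd = 1, seed = 7))
  for (nm in names(gens))
    expect_identical(gens[[nm]](), gens[[nm]](), label = nm)
  # and generators do not disturb the global RNG stream
  set.seed(42); before <- rnorm(3)
  set.seed(42); invisible(simSwimCohort(seed = 9)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noiseless beating-heart truth satisfies its closed forms", {
  sim <- noiselessVideoSim()
  p <- sim$truth$params
  expect_equal(max(sim$truth$frames$volume), p$edv, tolerance = 1e-12)
  # the frame clock need not hit end-systole exactly; minimum is close only
  expect_equal(min(sim$truth$frames$volume), p$esv, tolerance = 5e-3)
  expect_equal(sim$truth$ef, 0.5)
  # raised-cosine volume at every frame
  t <- sim$truth$frames$time
  v_expected <- p$esv + (p$edv - p$esv) *
    (1 + cos(2 * pi * p$heart_rate * t)) / 2
  expect_equal(sim$truth$frames$volume, v_expected, tolerance = 1e-9)
  # the biplane formula is exact on the ellipsoid ground truth
  v_biplane <- biplaneVolume(sim$truth$frames$short_area_mm2,
                             sim$truth$frames$long_length_mm)
  expect_equal(v_biplane, sim$truth$frames$volume, tolerance = 1e-9)
})

test_that("video generator rejects invalid parameters and tight framing", {
  expect_error(cardiacSimParams(edv = 2, esv = 2),
               class = "invalidParameterError")
  expect_error(cardiacSimParams(esv = -1), class = "invalidParameterError")
  expect_error(cardiacSimParams(heart_rate = 2, frame_rate = 3),
               class = "invalidParameterError")
  expect_error(cardiacSimParams(duration = 1),
               class = "invalidParameterError")
  expect_error(
    simBeatingHeartVideo(cardiacSimParams(image_shape = c(32L, 32L))),
    class = "renderingError")
})

test_that("noiseless myofibril trace follows its piecewise closed form", {
  p <- myofibrilSimParams(noise_sd = 0)
  sim <- simMyofibrilTrace(p)
  t <- sim$trace@time; f <- sim$trace@force
  ev <- p$event_times
  # activation asymptote: within 1% after 5/k_act, 0.1% by the release
  late <- t > ev[["activation"]] + 5 / p$k_act & t < ev[["release"]]
  expect_true(all(abs(f[late] - p$f_max) / p$f_max < 0.01))
  terminal <- f[max(which(t < ev[["release"]]))]
  expect_lt(abs(terminal - p$f_max) / p$f_max, 1e-3)
  # passive before activation
  expect_true(all(f[t < ev[["activation"]]] == p$f_passive))
  # redevelopment closed form at every sample
  red <- t >= ev[["restretch"]] & t < ev[["relaxation"]]
  expect_equal(f[red],
               sim$truth$plateau *
                 (1 - exp(-p$k_tr * (t[red] - ev[["restretch"]]))),
               tolerance = 1e-9)
})

test_that("t_lin = 0 degenerates to purely exponential relaxation", {
  p <- myofibrilSimParams(t_lin = 0, noise_sd = 0)
  sim <- simMyofibrilTrace(p)
  t <- sim$trace@time; f <- sim$trace@force
  rlx <- t >= p$event_times[["relaxation"]]
  tr <- t[rlx] - p$event_times[["relaxation"]]
  f0 <- sim$truth$relaxation_start_force
  expect_equal(f[rlx],
               p$f_passive + (f0 - p$f_passive) * exp(-p$k_rel * tr),
               tolerance = 1e-9)
})

test_that("myofibril generator enforces event ordering", {
  expect_error(
    myofibrilSimParams(event_times = c(activation = 1, release = 0.5,
                                       restretch = 2, relaxation = 3)),
    class = "eventOrderError")
  expect_error(myofibrilSimParams(f_max = 1, f_passive = 2),
               class = "invalidParameterError")
})

test_that("doppler waveform has half-sine lobes with the stated peaks", {
  p <- dopplerSimParams(e_peak = 10, a_peak = 5, noise_sd = 0)
  sim <- simDopplerWaveform(p)
  expect_equal(sim$truth$e_over_a, 2)
  # sampled maxima reach the stated peaks (up to sampling of the lobe apex)
  expect_equal(max(sim$waveform@velocity), 10, tolerance = 1e-3)
  # closed form at every sample of the first E lobe
  d0 <- p$ivct + p$et + p$ivrt
  lobe <- (p$period - d0) / 2
  t <- sim$waveform@time
  e1 <- t >= d0 & t < d0 + lobe
  expect_equal(sim$waveform@velocity[e1],
               10 * sin(pi * (t[e1] - d0) / lobe), tolerance = 1e-9)
  expect_equal(simDopplerWaveform(dopplerSimParams(e_peak = 7, a_peak = 7)
               )$truth$e_over_a, 1)
  expect_error(dopplerSimParams(ivct = 0.3, ivrt = 0.3, et = 0.3,
                                period = 0.5),
               class = "invalidParameterError")
})

test_that("swim cohort inverts the protocol exactly", {
  sw <- simSwimCohort(n = 12, ucrit_mean = 35, ucrit_sd = 5, seed = 3)
  rec <- computeUcrit(sw$trials$exhaustion_time_s)
  expect_equal(rec$ucrit, sw$truth$ucrit, tolerance = 1e-12)
  # sd = 0: all fish identical
  sw0 <- simSwimCohort(n = 5, ucrit_sd = 0, ucrit_mean = 30, seed = 1)
  expect_equal(diff(range(sw0$trials$exhaustion_time_s)), 0)
  # true Ucrit exactly at a stage boundary -> exhaustion at that stage end
  pr <- swimProtocol()
  swb <- simSwimCohort(n = 3, ucrit_sd = 0,
                       ucrit_mean = pr$initial_speed + 2 * pr$increment,
                       seed = 1)
  expect_equal(unique(swb$trials$exhaustion_time_s),
               2 * pr$stage_duration)
})

test_that("survival cohort honors hazards and censoring", {
  sv0 <- simSurvivalCohort(n_per_group = 10, hazards = c(a = 0, b = 0),
                           censor_time = 20, seed = 1)
  expect_true(all(sv0$event == 0))
  expect_true(all(sv0$time == 20))
  sv <- simSurvivalCohort(n_per_group = 50, hazards = c(a = 0.5, b = 0.5),
                          censor_time = 100, seed = 1)
  expect_true(mean(sv$event) > 0.9)
  expect_error(simSurvivalCohort(hazards = c(a = -1, b = 1)),
               class = "invalidParameterError")
})

test_that("labeled-image generators realize exact ground truth", {
  af <- simAreaFractionImage(shape = c(100L, 100L), fraction = 0.25,
                             seed = 2)
  expect_identical(sum(af$image), 2500L)
  expect_equal(af$truth$fraction, 0.25)

  nu0 <- simNucleiImage(n = 10, k = 0, seed = 2)
  expect_equal(nu0$truth$percent_positive, 0)

  cm <- simCellMasks(shape = c(64L, 64L), n = 1, side = 20, seed = 2)
  expect_equal(cellAreas(cm$labels, pixel_size = 1)$areas, 400)

  expect_error(simNucleiImage(shape = c(40L, 40L), n = 200, radius = 4),
               class = "infeasiblePackingError")
})

test_that("force-pCa generator matches the Hill form", {
  mid <- simForcePca(pca50 = 5.75, f_max = 40, pca_values = 5.75)
  expect_equal(mid$table$tension, 20)
  lowca <- simForcePca(pca50 = 6, n_h = 2, f_max = 40, pca_values = 10)
  expect_lt(lowca$table$tension, 1e-6 * 40)
  expect_error(simForcePca(n_h = 0), class = "invalidParameterError")
})
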