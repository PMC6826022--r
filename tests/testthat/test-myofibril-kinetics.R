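test_that("phase windows are bounded by the protocol marks", {
  sim <- simMyofibrilTrace(myofibrilSimParams(noise_sd = 0))
  ph <- segmentPhases(sim$trace)
  t <- sim$trace@time
  ev <- traceMarks(sim$trace)
  expect_equal(t[ph$activation[1]], ev[["activation"]], tolerance = 1e-3)
  expect_lt(max(t[ph$activation]), ev[["release"]])
  expect_equal(t[ph$relaxation[1]], ev[["relaxation"]], tolerance = 1e-3)

  bad <- sim$trace
  bad@marks[["release"]] <- ev[["restretch"]] + 1
  expect_error(segmentPhases(bad), class = "markOrderError")
  late <- ForceTrace(t, sim$trace@force,
                     marks = c(activation = 0.5, release = 3, restretch = 3.02,
                               relaxation = max(t) + 1))
  expect_error(segmentPhases(late), class = "missingMarkError")
})

test_that("exponential rise fit recovers the rate", {
  t <- seq(0, 2, by = 0.002)
  f <- 5 + 55 * (1 - exp(-5 * t))
  fit <- fitExponentialRise(t, f, baseline = 5)
  expect_equal(fit$rate, 5, tolerance = 1e-3)
  expect_equal(fit$plateau, 60, tolerance = 1e-3)
  expect_error(fitExponentialRise(t, rep(5, length(t)), baseline = 5),
               class = "insufficientRiseError")
  # invariance to time-origin shift and to force rescaling
  fit2 <- fitExponentialRise(t + 10, f, baseline = 5)
  expect_equal(fit2$rate, fit$rate, tolerance = 1e-9)
  fit3 <- fitExponentialRise(t, 3 * f, baseline = 15)
  expect_equal(fit3$rate, fit$rate, tolerance = 1e-6)
})

test_that("stochastic rise fits have small mean bias", {
  rates <- vapply(1:50, function(s) {
    t <- seq(0, 2, by = 0.002)
    f <- 5 + 55 * (1 - exp(-5 * t)) +
      withr::with_seed(s, rnorm(length(t), 0, 0.02 * 60))
    fitExponentialRise(t, f, baseline = 5)$rate
  }, numeric(1))
  expect_equal(mean(rates), 5, tolerance = 0.02)
})

test_that("biphasic relaxation fit recovers breakpoint and rates", {
  dt <- 0.001
  t <- seq(0, 2, by = dt)
  f0 <- 60; base <- 5; dev <- f0 - base
  t_lin <- 0.05; k_lin <- 1.2; k_rel <- 10
  fb <- f0 - k_lin * dev * t_lin
  f <- ifelse(t <= t_lin, f0 - k_lin * dev * t,
              base + (fb - base) * exp(-k_rel * (t - t_lin)))
  fit <- fitRelaxationBiphasic(t, f, plateau = f0, baseline = base)
  expect_lte(abs(fit$t_lin - t_lin), dt)
  expect_equal(fit$k_rel, k_rel, tolerance = 0.01)
  expect_equal(fit$k_lin, k_lin, tolerance = 0.02)

  # degenerate breakpoint: purely exponential decline
  fe <- base + dev * exp(-k_rel * t)
  fit0 <- fitRelaxationBiphasic(t, fe, plateau = f0, baseline = base)
  expect_lte(fit0$t_lin, dt)

  # pure linear decline: no identifiable exponential tail
  fl <- f0 - dev * t / 2
  expect_error(fitRelaxationBiphasic(t, fl, plateau = f0, baseline = base),
               class = "fitFailureError")

  # a window that mostly rises is flagged
  fr <- base + dev * (0.2 + 0.5 * t)
  expect_warning(
    try(fitRelaxationBiphasic(t, fr, plateau = f0, baseline = base),
        silent = TRUE),
    "non-monotone")
})

test_that("tension conversion and rundown QC follow their definitions", {
  expect_equal(computeTension(1005, 5, 100), 10)
  expect_equal(computeTension(5, 5, 100), 0)
  expect_error(computeTension(10, 5, 0), class = "nonPositiveCsaError")

  expect_true(qcRundown(c(100, 85))$include)     # 15% drop
  expect_false(qcRundown(c(100, 75))$include)    # 25% drop
  qc <- qcRundown(c(50, 50, 50))
  expect_true(qc$include)
  expect_equal(qc$rundown, 0)
  expect_error(qcRundown(100), class = "insufficientContractionsError")
})

test_that("Hill fit recovers force-pCa parameters to high precision", {
  sim <- simForcePca(pca50 = 5.75, n_h = 2, f_max = 35,
                     pca_values = seq(5.5, 6.0, by = 0.1), noise_sd = 0)
  fit <- fitHill(sim$table)
  expect_equal(fit$pca50, 5.75, tolerance = 1e-3)
  expect_equal(fit$n_h, 2, tolerance = 0.01)
  expect_lt(fit$sse / sum(sim$table$tension^2), 1e-10)
  # fitted curve passes through half-max at pca50
  half <- fit$f_max / (1 + 10^(fit$n_h * 0))
  expect_equal(half, fit$f_max / 2)
  expect_error(fitHill(data.frame(pca = c(5.5, 5.7, 5.9),
                                  tension = c(30, 20, 5))),
               class = "insufficientPointsError")
})

test_that("noiseless traces round-trip every kinetic parameter", {
  grids <- list(
    myofibrilSimParams(noise_sd = 0),
    myofibrilSimParams(k_act = 1.5, k_tr = 2.5, k_rel = 20, t_lin = 0.1,
                       k_lin_slope = 0.8, noise_sd = 0),
    myofibrilSimParams(f_max = 120, f_passive = 10, k_act = 6, k_tr = 8,
                       t_lin = 0.02, k_rel = 15, noise_sd = 0))
  for (p in grids) {
    sim <- simMyofibrilTrace(p)
    fit <- fitMyofibrilKinetics(sim$trace)
    expect_equal(fit$k_act, p$k_act, tolerance = 0.005)
    expect_equal(fit$k_tr, p$k_tr, tolerance = 0.005)
    expect_lte(abs(fit$t_lin - p$t_lin), 1 / p$sample_rate)
    expect_equal(fit$k_rel, p$k_rel, tolerance = 0.01)
    expect_equal(fit$k_lin, p$k_lin_slope, tolerance = 0.01)
    expect_equal(fit$max_tension, sim$truth$max_tension, tolerance = 0.005)
  }
})
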