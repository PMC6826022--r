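test_that("Ucrit implements the Brett form with the stage protocol", {
  # last completed stage 9 + 8.66 = 17.66 cm/s, 75 s into the next stage
  expect_equal(computeUcrit(150 + 75)$ucrit, 21.99)
  # exhaustion exactly at a stage boundary: Ucrit equals the completed speed
  expect_equal(computeUcrit(300)$ucrit, 9 + 2 * 8.66)
  # body-length normalization
  expect_equal(computeUcrit(150 + 75, body_length = 4)$ucrit_bl,
               21.99 / 4)
  expect_error(computeUcrit(1000, n_stages = 2),
               class = "protocolInconsistencyError")
})

test_that("Ucrit is invariant to consistent unit re-expression", {
  pr_cm <- swimProtocol(9, 8.66, 150)
  pr_m <- swimProtocol(0.09, 0.0866, 150)
  te <- c(37.5, 225, 410)
  expect_equal(computeUcrit(te, protocol = pr_m)$ucrit * 100,
               computeUcrit(te, protocol = pr_cm)$ucrit)
})

test_that("log-rank matches the hand-computed two-subject example", {
  rec <- data.frame(time = c(1, 1), event = c(1, 0),
                    group = c("A", "B"))
  lr <- kmLogrank(rec)
  expect_equal(lr$chisq, 1.0, tolerance = 1e-12)
  expect_equal(lr$df, 1)
  # identical event patterns in both groups: statistic 0
  same <- data.frame(time = rep(c(2, 5, 9), 2), event = rep(1, 6),
                     group = rep(c("A", "B"), each = 3))
  expect_equal(kmLogrank(same)$chisq, 0, tolerance = 1e-12)
})

test_that("KM curves are proper survival step functions", {
  sv <- simSurvivalCohort(n_per_group = 25,
                          hazards = c(wt = 0.02, mut = 0.08),
                          censor_time = 40, seed = 10)
  lr <- kmLogrank(sv)
  s <- lr$fit$surv
  strata_id <- rep(seq_along(lr$fit$strata), lr$fit$strata)
  for (g in unique(strata_id)) {
    sg <- s[strata_id == g]
    expect_true(all(diff(sg) <= 1e-12))       # non-increasing
    expect_lte(sg[1], 1)
    # one step per distinct event time within the stratum
    tg <- lr$fit$time[strata_id == g]
    ng <- lr$fit$n.event[strata_id == g]
    expect_equal(sum(diff(c(1, sg)) < -1e-12),
                 length(unique(tg[ng > 0])))
  }
})

test_that("degenerate survival inputs raise classed errors", {
  expect_error(kmLogrank(data.frame(time = 1:4, event = rep(1, 4),
                                    group = rep("A", 4))),
               class = "singleGroupError")
  expect_error(kmLogrank(data.frame(time = 1:4, event = rep(0, 4),
                                    group = rep(c("A", "B"), 2))),
               class = "allCensoredError")
})

test_that("group comparison reproduces classical statistics", {
  cg <- compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(cg$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(cg$df, 4)
  # identical groups: t = 0
  cg0 <- compareGroups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(cg0$statistic, 0)
  # one-way F on two groups equals t^2
  vals <- c(2.1, 3.3, 1.8, 4.2, 5.0, 4.8, 3.9, 2.2)
  grp <- rep(c("x", "y"), each = 4)
  tstat <- compareGroups(vals, grp)$statistic
  f3 <- stats::aov(vals ~ factor(grp))
  expect_equal(summary(f3)[[1]][["F value"]][1], tstat^2,
               tolerance = 1e-9)
  # three-group ANOVA carries a Tukey table
  cg3 <- compareGroups(c(1, 2, 3, 4, 5, 6, 9, 8, 7),
                       rep(c("a", "b", "c"), each = 3))
  expect_s3_class(cg3$tukey, "data.frame")
  expect_equal(nrow(cg3$tukey), 3)

  expect_error(compareGroups(1:3, c("a", "a", "b")),
               class = "insufficientDataError")
  expect_error(compareGroups(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
               class = "zeroVarianceError")
})
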