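#' Stepwise swim-tunnel protocol description
#'
#' The incremental swim protocol used for critical swimming speed: an
#' acclimation speed, then stepwise speed increments applied every
#' `stage_duration` seconds until exhaustion. Defaults are the protocol
#' this package targets: 9 cm/s acclimation, +8.66 cm/s every 150 s.
#'
#' @param initial_speed acclimation speed (cm/s), counted as the last
#'   completed stage for a fish exhausting during the first increment.
#' @param increment per-stage speed increment (cm/s).
#' @param stage_duration stage length (s).
#' @return A list of class `SwimProtocol`.
#' @export
swimProtocol <- function(initial_speed = 9, increment = 8.66,
                         stage_duration = 150) {
  checkScalar(initial_speed, "initial_speed", lower = 0, strict_lower = TRUE)
  checkScalar(increment, "increment", lower = 0, strict_lower = TRUE)
  checkScalar(stage_duration, "stage_duration", lower = 0,
              strict_lower = TRUE)
  structure(list(initial_speed = initial_speed, increment = increment,
                 stage_duration = stage_duration), class = "SwimProtocol")
}

#' Simulate a swim-tunnel cohort with known critical swimming speeds
#'
#' Draws each fish's true Ucrit from a normal distribution (truncated above
#' the acclimation speed) and inverts the Brett protocol so the recorded
#' exhaustion time reproduces that Ucrit exactly under [computeUcrit()].
#'
#' @param n number of fish.
#' @param ucrit_mean,ucrit_sd true Ucrit distribution (cm/s).
#' @param body_length body length (cm), recycled across fish.
#' @param protocol a [swimProtocol()].
#' @param seed integer seed.
#' @return A list with `trials` (data.frame `id`, `body_length_cm`,
#'   `exhaustion_time_s`) and `truth` (per-fish true Ucrit, cm/s).
#' @export
simSwimCohort <- function(n = 8, ucrit_mean = 35, ucrit_sd = 4,
                          body_length = 4, protocol = swimProtocol(),
                          seed = 1L) {
  checkScalar(n, "n", lower = 1)
  checkScalar(ucrit_sd, "ucrit_sd", lower = 0)
  checkScalar(ucrit_mean, "ucrit_mean",
              lower = protocol$initial_speed, strict_lower = TRUE)
  n <- as.integer(n)
  u0 <- protocol$initial_speed
  du <- protocol$increment
  ucrit <- fhWithSeed(seed, {
    u <- rnorm(n, ucrit_mean, ucrit_sd)
    # resample the (rare) draws at or below the acclimation speed
    for (i in seq_len(50)) {
      bad <- u <= u0
      if (!any(bad)) break
      u[bad] <- rnorm(sum(bad), ucrit_mean, ucrit_sd)
    }
    pmax(u, u0 + 1e-6)
  })
  stages <- (ucrit - u0) / du   # completed stages + fraction into final
  exhaustion <- stages * protocol$stage_duration
  list(trials = data.frame(id = seq_len(n),
                           body_length_cm = rep_len(body_length, n),
                           exhaustion_time_s = exhaustion),
       truth = list(ucrit = ucrit, protocol = protocol))
}

#' Simulate a multi-group survival cohort
#'
#' Exponential event times per group with administrative censoring.
#'
#' @param n_per_group subjects per group.
#' @param hazards named numeric vector of per-group hazards (events per unit
#'   time, >= 0); names become group labels. A zero hazard yields an
#'   all-censored group.
#' @param censor_time administrative censoring time.
#' @param seed integer seed.
#' @return data.frame with `id`, `group`, `time`, `event` (1 = death,
#'   0 = censored).
#' @export
simSurvivalCohort <- function(n_per_group = 30,
                              hazards = c(wt = 0.02, mut = 0.06),
                              censor_time = 30, seed = 1L) {
  checkScalar(n_per_group, "n_per_group", lower = 1)
  fhCheck(length(hazards) >= 1 && all(is.finite(hazards)) &&
          all(hazards >= 0), "invalidParameterError",
          "hazards must be finite and >= 0")
  checkScalar(censor_time, "censor_time", lower = 0, strict_lower = TRUE)
  n <- as.integer(n_per_group)
  if (is.null(names(hazards)))
    names(hazards) <- paste0("group", seq_along(hazards))
  fhWithSeed(seed, {
    recs <- lapply(names(hazards), function(g) {
      h <- hazards[[g]]
      tt <- if (h > 0) rexp(n, h) else rep(Inf, n)
      data.frame(group = g, time = pmin(tt, censor_time),
                 event = as.integer(tt <= censor_time))
    })
    out <- do.call(rbind, recs)
    out <- cbind(id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}
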