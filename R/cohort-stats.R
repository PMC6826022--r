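#' Critical swimming speed (Ucrit) from a stepwise swim trial
#'
#' Brett-form critical swimming speed:
#' `Ucrit = U_i + dU * (t / T)` where `U_i` is the speed of the last fully
#' completed stage, `dU` the stage increment, `t` the time swum into the
#' final (incomplete) stage and `T` the stage duration. A fish exhausting
#' during the first increment is credited with the acclimation speed as its
#' completed stage. When a body length is supplied the normalized value
#' `Ucrit / BL` (body lengths/s after unit conversion by the caller; here
#' cm/s over cm, so 1/s) is also returned.
#'
#' @param exhaustion_time time from the first increment to exhaustion (s);
#'   vectorized.
#' @param body_length body length (cm), optional; recycled.
#' @param protocol a [swimProtocol()].
#' @param n_stages number of increment stages actually run, optional; used
#'   to flag records whose exhaustion time exceeds the protocol.
#' @return data.frame with `ucrit` (cm/s) and `ucrit_bl` (body lengths/s,
#'   `NA` without body length).
#' @examples
#' # last completed stage 17.66 cm/s, 75 s into the next 150 s stage
#' computeUcrit(150 + 75)$ucrit  # 21.99
#' @export
computeUcrit <- function(exhaustion_time, body_length = NA_real_,
                         protocol = swimProtocol(), n_stages = NULL) {
  fhCheck(all(is.finite(exhaustion_time)) && all(exhaustion_time >= 0),
          "invalidParameterError",
          "exhaustion_time must be finite and >= 0")
  if (!is.null(n_stages) &&
      any(exhaustion_time > n_stages * protocol$stage_duration))
    fhStop("protocolInconsistencyError",
           "exhaustion time exceeds the recorded protocol stages")
  T <- protocol$stage_duration
  k <- floor(exhaustion_time / T)
  t_in <- exhaustion_time - k * T
  ui <- protocol$initial_speed + k * protocol$increment
  ucrit <- ui + protocol$increment * (t_in / T)
  bl <- rep_len(body_length, length(ucrit))
  data.frame(ucrit = ucrit, ucrit_bl = ucrit / bl)
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival estimates per group and the log-rank test
#' (observed-minus-expected form with hypergeometric variance summed over
#' distinct event times), with the p-value from a chi-squared distribution
#' on `groups - 1` degrees of freedom. Computation is delegated to the
#' survival package (`survfit`/`survdiff`).
#'
#' @param records data.frame with columns `time`, `event` (1 = death,
#'   0 = censored) and `group`.
#' @return A list: `fit` (a `survfit` object), `chisq`, `df`, `p`,
#'   `observed` and `expected` event counts per group.
#' @export
kmLogrank <- function(records) {
  fhCheck(is.data.frame(records) &&
          all(c("time", "event", "group") %in% names(records)),
          "invalidParameterError",
          "records needs columns time, event, group")
  fhCheck(all(records$event %in% c(0, 1)) && all(records$time >= 0),
          "invalidParameterError",
          "event must be 0/1 and time non-negative")
  groups <- unique(records$group)
  if (length(groups) < 2)
    fhStop("singleGroupError", "log-rank requires at least two groups")
  if (sum(records$event) == 0)
    fhStop("allCensoredError",
           "no events observed: log-rank statistic undefined")
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = records)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- length(groups) - 1
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Group comparison: t-test or one-way ANOVA with Tukey post hoc
#'
#' Two groups are compared by the unpaired two-tailed Student's t-test
#' (pooled variance); three or more by one-way ANOVA with Tukey's honest
#' significant difference post hoc table. Per-group means with standard
#' errors are reported alongside.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length.
#' @return A list of class `GroupComparison`: `test`, `statistic`, `df`,
#'   `p`, `group_summary` (mean, sem, n per group) and, for ANOVA,
#'   `tukey` (pairwise table).
#' @export
compareGroups <- function(values, groups) {
  fhCheck(length(values) == length(groups), "invalidParameterError",
          "values and groups must have equal length")
  groups <- factor(groups)
  ns <- table(groups)
  if (length(ns) < 2 || any(ns < 2))
    fhStop("insufficientDataError",
           "need >= 2 groups with >= 2 values each")
  gm <- tapply(values, groups, mean)
  gv <- tapply(values, groups, stats::var)
  if (all(gv == 0) && length(unique(gm)) > 1)
    fhStop("zeroVarianceError",
           "pooled variance is zero with unequal group means")
  gs <- data.frame(group = names(ns), n = as.integer(ns),
                   mean = as.numeric(gm),
                   sem = as.numeric(sqrt(gv / ns)))
  if (length(ns) == 2) {
    tt <- t.test(values ~ groups, var.equal = TRUE)
    out <- list(test = "Student t (unpaired, two-tailed)",
                statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                group_summary = gs)
  } else {
    fit <- aov(values ~ groups)
    an <- summary(fit)[[1]]
    out <- list(test = "one-way ANOVA + Tukey HSD",
                statistic = an[["F value"]][1],
                df = c(an[["Df"]][1], an[["Df"]][2]),
                p = an[["Pr(>F)"]][1],
                group_summary = gs,
                tukey = as.data.frame(TukeyHSD(fit)$groups))
  }
  structure(out, class = "GroupComparison")
}
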