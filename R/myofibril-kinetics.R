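#' Split a force trace into protocol phase windows
#'
#' Half-open windows `[mark_i, mark_{i+1})` derived from the protocol event
#' marks: baseline (before activation onset), activation, release,
#' redevelopment (restretch to relaxation onset) and relaxation (to trace
#' end).
#'
#' @param trace a [ForceTrace-class].
#' @return Named list of integer index vectors into the trace samples.
#' @export
segmentPhases <- function(trace) {
  fhCheck(is(trace, "ForceTrace"), "invalidParameterError",
          "trace must be a ForceTrace")
  need <- c("activation", "release", "restretch", "relaxation")
  m <- trace@marks[need]
  if (any(is.na(m)))
    fhStop("missingMarkError", "all four protocol marks are required")
  if (any(diff(m) <= 0))
    fhStop("markOrderError", "marks must be strictly increasing in time")
  t <- trace@time
  if (m[["activation"]] <= t[1] || m[["relaxation"]] >= t[length(t)])
    fhStop("missingMarkError", "marks fall outside the recorded trace")
  bounds <- c(t[1], m, t[length(t)] + .Machine$double.eps)
  nm <- c("baseline", "activation", "release", "redevelopment", "relaxation")
  out <- lapply(seq_along(nm), function(i)
    which(t >= bounds[i] & t < bounds[i + 1]))
  names(out) <- nm
  out
}

#' Fit a mono-exponential force rise
#'
#' Least-squares fit of `F(t) = F0 + (Finf - F0)(1 - exp(-k (t - t0)))` with
#' the starting level `F0` fixed at the supplied baseline and `t0` the
#' window start. Used both for the calcium-activation rate (k_ACT) and the
#' post-restretch force-redevelopment rate (k_TR). The rate is initialized
#' from the time to half-rise (`ln 2 / t_half`).
#'
#' @param time,force samples of the rise window (>= 10 samples).
#' @param baseline fixed starting force (nN).
#' @param min_rise smallest admissible rise `Finf - baseline` (nN) before
#'   the window is declared flat.
#' @return A list: `rate` (1/s), `plateau` (nN), `sse`, `converged`.
#' @export
fitExponentialRise <- function(time, force, baseline, min_rise = 1e-6) {
  fhCheck(length(time) >= 10 && length(time) == length(force),
          "fitFailureError", "need at least 10 matched samples")
  tt <- time - time[1]
  rise <- max(force) - baseline
  if (rise < min_rise)
    fhStop("insufficientRiseError",
           "window shows no force rise above the configured floor")
  half <- baseline + rise / 2
  i_half <- which(force >= half)[1]
  t_half <- max(tt[i_half], tt[2])
  df <- data.frame(tt = tt, force = force)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      force ~ baseline + (Finf - baseline) * (1 - exp(-k * tt)),
      data = df,
      start = list(Finf = baseline + rise, k = log(2) / t_half),
      lower = c(Finf = baseline, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e)
      fhStop("fitFailureError",
             paste("exponential rise fit failed:", conditionMessage(e))))
  cf <- coef(fit)
  if (cf[["k"]] <= 1e-8)
    fhStop("fitFailureError", "fitted rate is not positive")
  list(rate = unname(cf[["k"]]), plateau = unname(cf[["Finf"]]),
       sse = sum(stats::residuals(fit)^2), converged = TRUE)
}

# SSE of the fixed-amplitude exponential tail for a given log-rate
expTailSSE <- function(logk, tt, force, amp, baseline) {
  sum((force - (baseline + amp * exp(-exp(logk) * tt)))^2)
}

#' Fit the biphasic (linear-then-exponential) relaxation
#'
#' Piecewise model of myofibril relaxation: a slow linear decline for
#' `t in [0, t_lin]` followed by a single-exponential decay to the passive
#' baseline, continuous at the breakpoint. The breakpoint is chosen by a
#' coarse-then-fine grid search over the sample times minimizing the total
#' SSE (linear segment by ordinary least squares, exponential rate by 1-d
#' minimization with the amplitude pinned by continuity). The linear slope
#' is reported normalized by the developed force, so `k_lin` has units 1/s.
#'
#' @param time,force samples of the relaxation window (>= 20 samples).
#' @param plateau force at relaxation onset (nN).
#' @param baseline passive force (nN).
#' @param rel_tol maximal admissible exponential-segment RMSE as a fraction
#'   of the developed force before the fit is declared failed.
#' @return A list: `t_lin` (s), `k_lin` (1/s, normalized slope), `k_rel`
#'   (1/s), `sse`, `converged`.
#' @export
fitRelaxationBiphasic <- function(time, force, plateau, baseline,
                                  rel_tol = 0.05) {
  n <- length(time)
  fhCheck(n >= 20 && n == length(force), "fitFailureError",
          "need at least 20 matched samples")
  tt <- time - time[1]
  developed <- plateau - baseline
  fhCheck(developed > 0, "fitFailureError",
          "plateau must exceed baseline in a relaxation window")
  # material rises only: block-averaged so noise jitter is not a violation
  n_blocks <- min(20L, n %/% 5L)
  bm <- tapply(force, cut(seq_len(n), n_blocks), mean)
  if (mean(diff(bm) > 0.01 * developed) > 0.2)
    warning("non-monotone relaxation window: >20% of samples rise")

  evalCandidate <- function(i) {
    if (i <= 1L) {
      f_b <- force[1]; slope <- 0; sse_lin <- 0
    } else {
      fit <- stats::lm.fit(cbind(1, tt[1:i]), force[1:i])
      slope <- fit$coefficients[2]
      f_b <- fit$coefficients[1] + slope * tt[i]
      sse_lin <- sum(fit$residuals^2)
    }
    amp <- f_b - baseline
    jj <- i:n
    te <- tt[jj] - tt[i]
    if (amp <= 0) return(list(sse = Inf))
    op <- optimize(expTailSSE, interval = log(c(1e-3, 1e5)), tt = te,
                   force = force[jj], amp = amp, baseline = baseline)
    list(sse = sse_lin + op$objective, slope = slope,
         k = exp(op$minimum), sse_exp = op$objective, n_exp = length(jj),
         span = te[length(te)])
  }

  cand <- unique(c(1L, seq(1L, n - 10L, by = max(1L, (n - 10L) %/% 100L))))
  sses <- vapply(cand, function(i) evalCandidate(i)$sse, numeric(1))
  best <- cand[which.min(sses)]
  coarse_step <- max(1L, (n - 10L) %/% 100L)
  fine <- max(1L, best - coarse_step):min(n - 10L, best + coarse_step)
  sses_f <- vapply(fine, function(i) evalCandidate(i)$sse, numeric(1))
  i_best <- fine[which.min(sses_f)]
  res <- evalCandidate(i_best)

  if (!is.finite(res$sse))
    fhStop("fitFailureError", "no admissible breakpoint found")
  rmse_exp <- sqrt(res$sse_exp / res$n_exp)
  if (rmse_exp / developed > rel_tol)
    fhStop("fitFailureError",
           "exponential sub-fit does not describe the relaxation tail")
  if (res$k * res$span < 2)
    fhStop("fitFailureError",
           "relaxation tail too short or too linear to identify a rate")
  list(t_lin = tt[i_best], k_lin = unname(-res$slope / developed),
       k_rel = unname(res$k), sse = res$sse, converged = TRUE)
}

#' Maximal isometric tension
#'
#' Developed force normalized by myofibril cross-sectional area;
#' `1 nN/um^2 = 1 mN/mm^2`, so the value is reported in mN/mm^2 directly.
#'
#' @param plateau plateau force (nN).
#' @param baseline passive force (nN).
#' @param csa cross-sectional area (um^2), > 0.
#' @return Tension (mN/mm^2).
#' @examples
#' computeTension(1005, 5, 100)  # 10
#' @export
computeTension <- function(plateau, baseline, csa) {
  fhCheck(isScalarNum(csa) && csa > 0, "nonPositiveCsaError",
          "cross-sectional area must be positive")
  (plateau - baseline) / csa
}

#' Fit the force-pCa Hill relation
#'
#' Least-squares fit of `F(pCa) = F_max / (1 + 10^(n_h (pCa - pca50)))`,
#' initialized at `n_h = 2` and `pca50` at the pCa whose tension is closest
#' to half-maximum.
#'
#' @param table data.frame with columns `pca` and `tension` (>= 4 distinct
#'   pCa values).
#' @return A list of class `HillFit`: `pca50`, `n_h`, `f_max`, `sse`.
#' @export
fitHill <- function(table) {
  fhCheck(is.data.frame(table) && all(c("pca", "tension") %in% names(table)),
          "invalidParameterError", "table needs columns 'pca' and 'tension'")
  fhCheck(length(unique(table$pca)) >= 4, "insufficientPointsError",
          "at least 4 distinct pCa values are required")
  f0 <- max(table$tension)
  p0 <- table$pca[which.min(abs(table$tension - f0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      tension ~ fmax / (1 + 10^(nh * (pca - pca50))),
      data = table,
      start = list(fmax = f0, nh = 2, pca50 = p0),
      lower = c(fmax = 0, nh = 1e-3, pca50 = min(table$pca) - 1),
      upper = c(fmax = Inf, nh = Inf, pca50 = max(table$pca) + 1),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
    error = function(e)
      fhStop("fitFailureError",
             paste("Hill fit failed:", conditionMessage(e))))
  cf <- coef(fit)
  structure(list(pca50 = unname(cf[["pca50"]]), n_h = unname(cf[["nh"]]),
                 f_max = unname(cf[["fmax"]]),
                 sse = sum(stats::residuals(fit)^2)),
            class = "HillFit")
}

#' Rundown quality control for a myofibril contraction set
#'
#' A fiber is excluded when the developed tension declines by more than 20%
#' over a set of contractions: `rundown = (first - last)/first`.
#'
#' @param tensions developed tensions, in contraction order (>= 2 values).
#' @param max_rundown exclusion threshold (default 0.20).
#' @return A list with `include` (logical) and `rundown` (fraction).
#' @examples
#' qcRundown(c(100, 85))$include  # TRUE  (15% drop)
#' qcRundown(c(100, 75))$include  # FALSE (25% drop)
#' @export
qcRundown <- function(tensions, max_rundown = 0.20) {
  fhCheck(length(tensions) >= 2, "insufficientContractionsError",
          "at least 2 contractions are required")
  fhCheck(tensions[1] > 0, "invalidParameterError",
          "first developed tension must be positive")
  rundown <- (tensions[1] - tensions[length(tensions)]) / tensions[1]
  list(include = rundown <= max_rundown, rundown = rundown)
}

#' Fit the full kinetic profile of one force trace
#'
#' Orchestrates the phase segmentation and the individual fits:
#' passive baseline from the pre-activation window, activation rate (k_ACT)
#' from the activation window, redevelopment rate (k_TR) from the
#' post-restretch window (its own starting force taken from the first
#' window sample), and the biphasic relaxation (T_LIN, k_LIN, k_REL) from
#' the relaxation window. Maximal tension is computed when the trace carries
#' a cross-sectional area.
#'
#' @param trace a [ForceTrace-class].
#' @param rel_tol see [fitRelaxationBiphasic()].
#' @return A list of class `KineticsResult`: `k_act`, `k_tr`, `t_lin`,
#'   `k_lin`, `k_rel` (1/s or s), `plateau`, `baseline` (nN),
#'   `max_tension` (mN/mm^2, `NA` without CSA), and `diagnostics` (per-fit
#'   SSEs and convergence flags).
#' @export
fitMyofibrilKinetics <- function(trace, rel_tol = 0.05) {
  ph <- segmentPhases(trace)
  t <- trace@time; f <- trace@force
  baseline <- mean(f[ph$baseline])

  act <- fitExponentialRise(t[ph$activation], f[ph$activation], baseline)
  red <- fitExponentialRise(t[ph$redevelopment], f[ph$redevelopment],
                            baseline = f[ph$redevelopment][1])
  rlx <- fitRelaxationBiphasic(t[ph$relaxation], f[ph$relaxation],
                               plateau = f[ph$relaxation][1],
                               baseline = baseline, rel_tol = rel_tol)
  max_tension <- if (!is.na(trace@csa))
    computeTension(act$plateau, baseline, trace@csa) else NA_real_
  structure(list(k_act = act$rate, k_tr = red$rate,
                 t_lin = rlx$t_lin, k_lin = rlx$k_lin, k_rel = rlx$k_rel,
                 plateau = act$plateau, baseline = baseline,
                 max_tension = max_tension,
                 diagnostics = list(sse_act = act$sse, sse_tr = red$sse,
                                    sse_relax = rlx$sse,
                                    converged = c(act = act$converged,
                                                  tr = red$converged,
                                                  relax = rlx$converged))),
            class = "KineticsResult")
}
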