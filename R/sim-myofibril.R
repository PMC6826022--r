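#' Simulation parameters for a single-myofibril force transient
#'
#' Parameter set for [simMyofibrilTrace()]. The defaults emulate a mounted
#' single myofibril at 10 C, sarcomere length 2.3 um, activated by a fast
#' pCa 10 -> 4.5 solution switch, subjected to a rapid release-restretch
#' maneuver at the force plateau, and relaxed by switching back to pCa 10.
#'
#' The noiseless trace is piecewise closed-form:
#' passive force before activation; mono-exponential rise at rate `k_act`
#' toward `f_max`; force dropped to zero during the release; mono-exponential
#' redevelopment at rate `k_tr` back to the plateau after the restretch; then
#' biphasic relaxation — a linear decline of normalized slope `k_lin_slope`
#' (fraction of developed force per second) lasting `t_lin`, followed by a
#' single-exponential decay at rate `k_rel` to the passive level.
#'
#' @param f_max calcium-saturated force asymptote (nN).
#' @param f_passive passive force (nN); `0 <= f_passive < f_max`.
#' @param k_act activation (calcium-induced force development) rate (1/s).
#' @param k_tr post-restretch force redevelopment rate (1/s).
#' @param t_lin duration of the slow linear relaxation phase (s).
#' @param k_lin_slope linear-phase decline, as fraction of developed force
#'   per second (1/s).
#' @param k_rel fast exponential relaxation rate (1/s).
#' @param csa myofibril cross-sectional area (um^2).
#' @param event_times named numeric vector of protocol event onsets (s):
#'   `activation`, `release`, `restretch`, `relaxation`, strictly increasing.
#' @param duration trace length (s); must extend past the relaxation mark.
#' @param sample_rate sampling rate (samples/s).
#' @param noise_sd Gaussian force noise, as a fraction of `f_max`.
#' @param sarcomere_length sarcomere length (um), metadata.
#' @param temperature bath temperature (C), metadata.
#' @param seed integer seed.
#' @return A validated list of class `MyofibrilSimParams`.
#' @export
myofibrilSimParams <- function(f_max = 60, f_passive = 5, k_act = 3,
                               k_tr = 4, t_lin = 0.05, k_lin_slope = 1.2,
                               k_rel = 10, csa = 1.5,
                               event_times = c(activation = 0.5,
                                               release = 3.0,
                                               restretch = 3.02,
                                               relaxation = 5.0),
                               duration = 7, sample_rate = 1000,
                               noise_sd = 0, sarcomere_length = 2.3,
                               temperature = 10, seed = 1L) {
  checkScalar(f_passive, "f_passive", lower = 0)
  checkScalar(f_max, "f_max", lower = f_passive, strict_lower = TRUE)
  for (nm in c("k_act", "k_tr", "k_rel", "k_lin_slope", "sample_rate", "csa"))
    checkScalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  checkScalar(t_lin, "t_lin", lower = 0)
  need <- c("activation", "release", "restretch", "relaxation")
  fhCheck(all(need %in% names(event_times)), "invalidParameterError",
          "event_times must name activation, release, restretch, relaxation")
  ev <- event_times[need]
  fhCheck(all(diff(ev) > 0), "eventOrderError",
          "event_times must be strictly increasing")
  checkScalar(duration, "duration", lower = ev[["relaxation"]],
              strict_lower = TRUE)
  checkScalar(noise_sd, "noise_sd", lower = 0)
  structure(list(f_max = f_max, f_passive = f_passive, k_act = k_act,
                 k_tr = k_tr, t_lin = t_lin, k_lin_slope = k_lin_slope,
                 k_rel = k_rel, csa = csa, event_times = ev,
                 duration = duration, sample_rate = sample_rate,
                 noise_sd = noise_sd, sarcomere_length = sarcomere_length,
                 temperature = temperature, seed = as.integer(seed)),
            class = "MyofibrilSimParams")
}

#' Simulate a single-myofibril force transient with ground truth
#'
#' @param params a [myofibrilSimParams()] object.
#' @return A list with `trace` (a [ForceTrace-class]) and `truth`
#'   (the generating rates plus the derived plateau force, relaxation start
#'   force and maximal tension in mN/mm^2).
#' @examples
#' sim <- simMyofibrilTrace(myofibrilSimParams(noise_sd = 0))
#' fit <- fitMyofibrilKinetics(sim$trace)
#' c(fit$k_tr, sim$truth$k_tr)
#' @export
simMyofibrilTrace <- function(params) {
  fhCheck(inherits(params, "MyofibrilSimParams"), "invalidParameterError",
          "params must come from myofibrilSimParams()")
  p <- params
  ev <- p$event_times
  t <- seq(0, p$duration, by = 1 / p$sample_rate)
  f <- rep(p$f_passive, length(t))
  dev_amp <- p$f_max - p$f_passive

  act <- t >= ev[["activation"]] & t < ev[["release"]]
  f[act] <- p$f_passive +
    dev_amp * (1 - exp(-p$k_act * (t[act] - ev[["activation"]])))

  # plateau actually reached before the release (= f_max for long activations)
  plateau <- p$f_passive +
    dev_amp * (1 - exp(-p$k_act * (ev[["release"]] - ev[["activation"]])))

  rel <- t >= ev[["release"]] & t < ev[["restretch"]]
  f[rel] <- 0

  red <- t >= ev[["restretch"]] & t < ev[["relaxation"]]
  f[red] <- plateau * (1 - exp(-p$k_tr * (t[red] - ev[["restretch"]])))

  f0 <- plateau * (1 - exp(-p$k_tr * (ev[["relaxation"]] - ev[["restretch"]])))
  developed <- f0 - p$f_passive
  rlx <- t >= ev[["relaxation"]]
  tr <- t[rlx] - ev[["relaxation"]]
  lin <- f0 - p$k_lin_slope * developed * pmin(tr, p$t_lin)
  f_break <- f0 - p$k_lin_slope * developed * p$t_lin
  f[rlx] <- ifelse(tr <= p$t_lin, lin,
                   p$f_passive + (f_break - p$f_passive) *
                     exp(-p$k_rel * (tr - p$t_lin)))

  if (p$noise_sd > 0)
    f <- f + fhWithSeed(p$seed, rnorm(length(f), 0, p$noise_sd * p$f_max))

  trace <- ForceTrace(t, f, marks = ev, csa = p$csa,
                      sarcomereLength = p$sarcomere_length,
                      temperature = p$temperature)
  truth <- list(k_act = p$k_act, k_tr = p$k_tr, t_lin = p$t_lin,
                k_lin = p$k_lin_slope, k_rel = p$k_rel,
                f_max = p$f_max, f_passive = p$f_passive,
                plateau = plateau, relaxation_start_force = f0,
                max_tension = (p$f_max - p$f_passive) / p$csa,
                params = p)
  list(trace = trace, truth = truth)
}

#' Simulate a force-pCa table from the Hill relation
#'
#' Generates steady-state tensions at a set of pCa values (defaults span the
#' activating-buffer range pCa 5.5-6 at sarcomere length 2.0 um) from
#' `tension(pCa) = f_max / (1 + 10^(n_h (pCa - pca50)))`, plus optional
#' Gaussian noise.
#'
#' @param pca50 pCa at half-maximal tension.
#' @param n_h Hill coefficient (> 0).
#' @param f_max maximal tension (mN/mm^2).
#' @param pca_values pCa grid (non-empty).
#' @param noise_sd Gaussian tension noise, absolute units.
#' @param seed integer seed.
#' @return A list with `table` (data.frame `pca`, `tension`) and `truth`.
#' @export
simForcePca <- function(pca50 = 5.75, n_h = 2, f_max = 35,
                        pca_values = seq(5.5, 6, by = 0.1),
                        noise_sd = 0, seed = 1L) {
  checkScalar(n_h, "n_h", lower = 0, strict_lower = TRUE)
  checkScalar(f_max, "f_max", lower = 0, strict_lower = TRUE)
  checkScalar(pca50, "pca50")
  fhCheck(length(pca_values) >= 1 && all(is.finite(pca_values)),
          "invalidParameterError", "pca_values must be non-empty and finite")
  checkScalar(noise_sd, "noise_sd", lower = 0)
  tension <- f_max / (1 + 10^(n_h * (pca_values - pca50)))
  if (noise_sd > 0)
    tension <- tension +
      fhWithSeed(seed, rnorm(length(tension), 0, noise_sd))
  list(table = data.frame(pca = pca_values, tension = tension),
       truth = list(pca50 = pca50, n_h = n_h, f_max = f_max))
}
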