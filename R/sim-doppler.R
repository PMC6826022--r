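#' Simulation parameters for a Doppler inflow waveform
#'
#' Parameter set for [simDopplerWaveform()]. Each cardiac cycle is laid out
#' as: atrioventricular (AV) valve closure at the cycle start, isovolumic
#' contraction (`ivct`), ejection (`et`, ventriculobulbar valve open),
#' isovolumic relaxation (`ivrt`), then diastole filling the remainder of
#' the period with an early (E) half-sine inflow lobe followed by a late
#' atrial (A) lobe of equal duration. The inflow velocity is zero outside
#' the two diastolic lobes.
#'
#' Defaults emulate a ~3 s pulsed-wave recording of an anesthetized adult
#' zebrafish with E-dominant filling.
#'
#' @param e_peak early (passive) filling peak velocity (mm/s).
#' @param a_peak atrial (active) filling peak velocity (mm/s).
#' @param ivct isovolumic contraction time (s).
#' @param ivrt isovolumic relaxation time (s).
#' @param et ejection time (s); `ivct + ivrt + et < period`.
#' @param period cardiac period (s).
#' @param n_cycles number of cycles.
#' @param sample_rate samples/s.
#' @param noise_sd additive Gaussian velocity noise (mm/s).
#' @param seed integer seed.
#' @return A validated list of class `DopplerSimParams`.
#' @export
dopplerSimParams <- function(e_peak = 25, a_peak = 12, ivct = 0.03,
                             ivrt = 0.04, et = 0.18, period = 0.5,
                             n_cycles = 6, sample_rate = 1000,
                             noise_sd = 0, seed = 1L) {
  checkScalar(e_peak, "e_peak", lower = 0, strict_lower = TRUE)
  checkScalar(a_peak, "a_peak", lower = 0, strict_lower = TRUE)
  checkScalar(ivct, "ivct", lower = 0)
  checkScalar(ivrt, "ivrt", lower = 0)
  checkScalar(et, "et", lower = 0, strict_lower = TRUE)
  checkScalar(period, "period", lower = ivct + ivrt + et,
              strict_lower = TRUE)
  checkScalar(n_cycles, "n_cycles", lower = 1)
  checkScalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  checkScalar(noise_sd, "noise_sd", lower = 0)
  structure(list(e_peak = e_peak, a_peak = a_peak, ivct = ivct,
                 ivrt = ivrt, et = et, period = period,
                 n_cycles = as.integer(n_cycles),
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "DopplerSimParams")
}

#' Simulate a ventricular inflow Doppler waveform with ground truth
#'
#' @param params a [dopplerSimParams()] object.
#' @return A list with `waveform` (a [DopplerWaveform-class] carrying
#'   per-cycle valve-event annotations) and `truth` (generating peaks,
#'   intervals, `e_over_a` and `mpi`).
#' @examples
#' sim <- simDopplerWaveform(dopplerSimParams(e_peak = 10, a_peak = 5))
#' sim$truth$e_over_a  # 2
#' @export
simDopplerWaveform <- function(params) {
  fhCheck(inherits(params, "DopplerSimParams"), "invalidParameterError",
          "params must come from dopplerSimParams()")
  p <- params
  t <- seq(0, p$n_cycles * p$period, by = 1 / p$sample_rate)
  v <- numeric(length(t))
  d_start <- p$ivct + p$et + p$ivrt        # diastole onset within a cycle
  d_len <- p$period - d_start
  lobe <- d_len / 2
  for (k in seq_len(p$n_cycles)) {
    t0 <- (k - 1) * p$period + d_start
    e_idx <- t >= t0 & t < t0 + lobe
    v[e_idx] <- p$e_peak * sin(pi * (t[e_idx] - t0) / lobe)
    a_idx <- t >= t0 + lobe & t < t0 + 2 * lobe
    v[a_idx] <- p$a_peak * sin(pi * (t[a_idx] - t0 - lobe) / lobe)
  }
  if (p$noise_sd > 0)
    v <- v + fhWithSeed(p$seed, rnorm(length(v), 0, p$noise_sd))

  k <- seq_len(p$n_cycles) - 1
  events <- data.frame(cycle = k + 1,
                       av_close = k * p$period,
                       vb_open = k * p$period + p$ivct,
                       vb_close = k * p$period + p$ivct + p$et,
                       av_open = k * p$period + d_start)
  truth <- list(e_peak = p$e_peak, a_peak = p$a_peak,
                e_over_a = p$e_peak / p$a_peak,
                ivct = p$ivct, ivrt = p$ivrt, et = p$et,
                mpi = (p$ivct + p$ivrt) / p$et, params = p)
  list(waveform = DopplerWaveform(t, v, events), truth = truth)
}
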