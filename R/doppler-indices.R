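#' Detect E and A inflow peaks and the E/A ratio
#'
#' Finds the diastolic inflow lobes as contiguous stretches of velocity
#' above a small fraction of the waveform maximum. Within each cardiac
#' cycle the first lobe is the early (E) wave and the second the atrial (A)
#' wave, so lobes are paired sequentially; the ratio is
#' `mean(E peaks) / mean(A peaks)` over all complete cycles.
#'
#' @param waveform a [DopplerWaveform-class].
#' @param threshold_frac lobe-detection threshold as a fraction of the
#'   maximal velocity.
#' @return A list with per-cycle `e_peaks` and `a_peaks` (mm/s), mean `e`,
#'   mean `a`, and `e_over_a`.
#' @export
detectEAPeaks <- function(waveform, threshold_frac = 0.05) {
  fhCheck(is(waveform, "DopplerWaveform"), "invalidParameterError",
          "waveform must be a DopplerWaveform")
  v <- waveform@velocity
  vmax <- max(v)
  fhCheck(vmax > 0, "lobeDetectionError", "waveform has no positive inflow")
  above <- v > threshold_frac * vmax
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])
  if (nrow(segs) < 2)
    fhStop("lobeDetectionError", "fewer than two inflow lobes detected")
  if (nrow(segs) %% 2 != 0)
    fhStop("lobeDetectionError",
           "odd lobe count: cannot pair E and A waves per cycle")
  peaks <- apply(segs, 1, function(s) max(v[s[1]:s[2]]))
  e_peaks <- peaks[seq(1, length(peaks), by = 2)]
  a_peaks <- peaks[seq(2, length(peaks), by = 2)]
  list(e_peaks = e_peaks, a_peaks = a_peaks,
       e = mean(e_peaks), a = mean(a_peaks),
       e_over_a = mean(e_peaks) / mean(a_peaks))
}

#' Myocardial performance index (Tei index)
#'
#' `MPI = (IVCT + IVRT) / ET`. The MPI integrates systolic and diastolic
#' performance; higher values indicate worse global cardiac function. As a
#' ratio of time intervals it is dimensionless and invariant under a common
#' rescaling of all three inputs.
#'
#' @param ivct isovolumic contraction time (s), >= 0.
#' @param ivrt isovolumic relaxation time (s), >= 0.
#' @param et ejection time (s), > 0.
#' @return MPI (dimensionless).
#' @examples
#' computeMPI(0.020, 0.030, 0.100)  # 0.5
#' @export
computeMPI <- function(ivct, ivrt, et) {
  fhCheck(all(is.finite(c(ivct, ivrt, et))) && all(ivct >= 0) &&
          all(ivrt >= 0), "invalidParameterError",
          "ivct and ivrt must be finite and non-negative")
  fhCheck(all(et > 0), "zeroETError", "ejection time must be positive")
  (ivct + ivrt) / et
}

#' Doppler diastolic and global-function indices
#'
#' Computes E, A and E/A from the inflow lobes, and — when per-cycle valve
#' annotations are present — IVCT, IVRT, ET and the MPI, averaged over all
#' annotated cycles. Without annotations the interval indices are `NA`:
#' the inflow trace alone does not expose the valve events, and no
#' detection rule is guessed.
#'
#' @param waveform a [DopplerWaveform-class].
#' @param threshold_frac see [detectEAPeaks()].
#' @return A list of class `DopplerIndices`: `e`, `a`, `e_over_a` (mm/s,
#'   ratio), `ivct`, `ivrt`, `et` (s), `mpi`.
#' @export
dopplerIndices <- function(waveform, threshold_frac = 0.05) {
  ea <- detectEAPeaks(waveform, threshold_frac)
  ev <- waveform@events
  if (nrow(ev)) {
    ivct <- mean(ev$vb_open - ev$av_close)
    et <- mean(ev$vb_close - ev$vb_open)
    ivrt <- mean(ev$av_open - ev$vb_close)
    mpi <- computeMPI(ivct, ivrt, et)
  } else ivct <- ivrt <- et <- mpi <- NA_real_
  structure(list(e = ea$e, a = ea$a, e_over_a = ea$e_over_a,
                 ivct = ivct, ivrt = ivrt, et = et, mpi = mpi),
            class = "DopplerIndices")
}
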