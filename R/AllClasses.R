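#' BiplaneVideo: two orthogonal views of a beating ventricle
#'
#' Container for a paced ex vivo heart filmed simultaneously in a long-axis
#' and a short-axis (transverse) plane, as acquired with a camera plus a
#' 45-degree mirror. Each plane is a numeric array `rows x cols x frames`
#' with intensities on `[0, 1]`; both planes share the frame clock.
#'
#' @slot planeLong numeric array, long-axis image stack (rows x cols x frames).
#' @slot planeShort numeric array, short-axis image stack; same frame count.
#' @slot pixelSize physical size of one pixel (mm/pixel).
#' @slot frameRate acquisition rate (frames/s).
#'
#' @seealso [simBeatingHeartVideo()], [summarizeHeart()]
#' @export
setClass("BiplaneVideo",
  representation(planeLong = "array", planeShort = "array",
                 pixelSize = "numeric", frameRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@planeLong)) != 3L ||
        length(dim(object@planeShort)) != 3L)
      msg <- c(msg, "both planes must be 3-d arrays (rows x cols x frames)")
    else if (dim(object@planeLong)[3] != dim(object@planeShort)[3])
      msg <- c(msg, "planes must have the same frame count")
    if (!isScalarNum(object@pixelSize) || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a positive scalar")
    if (!isScalarNum(object@frameRate) || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct a BiplaneVideo
#'
#' @param planeLong,planeShort numeric arrays (rows x cols x frames).
#' @param pixelSize mm/pixel.
#' @param frameRate frames/s.
#' @return A [BiplaneVideo-class] object.
#' @export
BiplaneVideo <- function(planeLong, planeShort, pixelSize, frameRate) {
  new("BiplaneVideo", planeLong = planeLong, planeShort = planeShort,
      pixelSize = pixelSize, frameRate = frameRate)
}

#' ForceTrace: a single-myofibril force record
#'
#' Time-stamped force record from a mounted single myofibril with the
#' protocol event marks needed for kinetic fitting: calcium activation onset
#' (fast pCa 10 to 4.5 switch), the rapid release, the restretch, and the
#' relaxation onset (switch back to pCa 10).
#'
#' @slot time sample times (s), strictly increasing.
#' @slot force force (nN).
#' @slot marks named numeric: `activation`, `release`, `restretch`,
#'   `relaxation` event times (s), strictly ordered.
#' @slot csa myofibril cross-sectional area (um^2); `NA` when not measured.
#' @slot sarcomereLength sarcomere length (um); `NA` when not recorded.
#' @slot temperature bath temperature (degrees C); `NA` when not recorded.
#'
#' @seealso [simMyofibrilTrace()], [fitMyofibrilKinetics()]
#' @export
setClass("ForceTrace",
  representation(time = "numeric", force = "numeric", marks = "numeric",
                 csa = "numeric", sarcomereLength = "numeric",
                 temperature = "numeric"),
  prototype(csa = NA_real_, sarcomereLength = NA_real_,
            temperature = NA_real_),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@force))
      msg <- c(msg, "time and force must have equal length")
    if (length(object@time) > 1L && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    need <- c("activation", "release", "restretch", "relaxation")
    if (!all(need %in% names(object@marks)))
      msg <- c(msg, "marks must name activation, release, restretch, relaxation")
    else {
      m <- object@marks[need]
      if (all(is.finite(m)) && any(diff(m) <= 0))
        msg <- c(msg, "marks must be strictly ordered in time")
    }
    if (!is.na(object@csa) && object@csa <= 0)
      msg <- c(msg, "csa must be positive when given")
    if (length(msg)) msg else TRUE
  })

#' Construct a ForceTrace
#'
#' @param time sample times (s).
#' @param force force (nN).
#' @param marks named numeric vector of event times (s) with names
#'   `activation`, `release`, `restretch`, `relaxation`.
#' @param csa cross-sectional area (um^2), optional.
#' @param sarcomereLength sarcomere length (um), optional.
#' @param temperature bath temperature (C), optional.
#' @return A [ForceTrace-class] object.
#' @export
ForceTrace <- function(time, force, marks, csa = NA_real_,
                       sarcomereLength = NA_real_, temperature = NA_real_) {
  new("ForceTrace", time = as.numeric(time), force = as.numeric(force),
      marks = marks, csa = csa, sarcomereLength = sarcomereLength,
      temperature = temperature)
}

#' DopplerWaveform: ventricular inflow velocity trace
#'
#' Pulsed-wave Doppler inflow velocity sampled over one or more cardiac
#' cycles, optionally annotated with valve event times (atrioventricular
#' valve close/open and ventriculobulbar valve open/close) that bound the
#' isovolumic contraction time, ejection time and isovolumic relaxation time.
#'
#' @slot time sample times (s), strictly increasing.
#' @slot velocity inflow velocity (mm/s).
#' @slot events data.frame with one row per cycle and columns `av_close`,
#'   `vb_open`, `vb_close`, `av_open` (s); zero rows when unannotated.
#'
#' @seealso [simDopplerWaveform()], [dopplerIndices()]
#' @export
setClass("DopplerWaveform",
  representation(time = "numeric", velocity = "numeric",
                 events = "data.frame"),
  prototype(events = data.frame()),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@velocity))
      msg <- c(msg, "time and velocity must have equal length")
    if (length(object@time) > 1L && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (nrow(object@events) &&
        !all(c("av_close", "vb_open", "vb_close", "av_open") %in%
             names(object@events)))
      msg <- c(msg, "events must have av_close, vb_open, vb_close, av_open")
    if (length(msg)) msg else TRUE
  })

#' Construct a DopplerWaveform
#'
#' @param time sample times (s).
#' @param velocity inflow velocity (mm/s).
#' @param events optional per-cycle valve-event data.frame (columns
#'   `av_close`, `vb_open`, `vb_close`, `av_open`, seconds).
#' @return A [DopplerWaveform-class] object.
#' @export
DopplerWaveform <- function(time, velocity, events = data.frame()) {
  new("DopplerWaveform", time = as.numeric(time),
      velocity = as.numeric(velocity), events = events)
}

#' HeartFunctionSummary: per-heart averaged functional indices
#'
#' Per-cycle table and across-cycle means for a single analyzed heart:
#' end-diastolic/end-systolic volumes (mm^3), ejection fraction, fractional
#' shortening, fractional area change, maximal contraction and relaxation
#' strain-rate velocities (1/s), and velocity-strain loop area (strain^2/s).
#'
#' @slot cycles per-cycle data.frame (one row per analyzed cardiac cycle).
#' @slot means named numeric vector of arithmetic means over analyzed cycles.
#'
#' @seealso [summarizeHeart()]
#' @export
setClass("HeartFunctionSummary",
  representation(cycles = "data.frame", means = "numeric"),
  validity = function(object) {
    if (nrow(object@cycles) < 3L)
      "at least 3 analyzed cycles are required" else TRUE
  })
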