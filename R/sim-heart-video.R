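#' Simulation parameters for a paced beating-heart video
#'
#' Parameter set for [simBeatingHeartVideo()]. The defaults emulate the ex
#' vivo acquisition protocol this package targets: a ventricle paced at 2 Hz
#' and filmed at 66 fps for 3 s in two orthogonal planes (long axis directly,
#' short axis via a 45-degree mirror).
#'
#' The chamber is modelled as a prolate ellipsoid with equal short semi-axes
#' `a = b` and long semi-axis `c = axis_ratio * a`, so the biplane
#' area-length estimate `V = 2/3 * (pi a^2) * (2 c)` is exact and ground
#' truth is analytic. The volume follows a raised cosine between EDV and ESV
#' (end-diastole at t = 0).
#'
#' @param edv end-diastolic volume (mm^3).
#' @param esv end-systolic volume (mm^3); `0 < esv < edv`.
#' @param heart_rate pacing rate (beats/s).
#' @param frame_rate acquisition rate (frames/s); must exceed `2*heart_rate`.
#' @param duration recording length (s); must cover at least 3 cycles.
#' @param pixel_size mm/pixel.
#' @param image_shape integer `c(rows, cols)` of each frame.
#' @param noise_sd additive Gaussian pixel noise, on the `[0, 1]` gray scale.
#' @param blur_sigma Gaussian optical blur (pixels); 0 disables.
#' @param axis_ratio long-to-short semi-axis ratio `c/a` of the ellipsoid.
#' @param fg,bg foreground (myocardium) and background gray levels in `[0,1]`.
#' @param seed integer seed; every random draw flows from it.
#' @return A validated list of class `CardiacSimParams`.
#' @export
cardiacSimParams <- function(edv = 4, esv = 2, heart_rate = 2,
                             frame_rate = 66, duration = 3,
                             pixel_size = 0.025, image_shape = c(160L, 160L),
                             noise_sd = 0.02, blur_sigma = 1,
                             axis_ratio = 1.5, fg = 0.8, bg = 0.1,
                             seed = 1L) {
  checkScalar(esv, "esv", lower = 0, strict_lower = TRUE)
  checkScalar(edv, "edv", lower = esv, strict_lower = TRUE)
  checkScalar(heart_rate, "heart_rate", lower = 0, strict_lower = TRUE)
  checkScalar(frame_rate, "frame_rate", lower = 2 * heart_rate,
              strict_lower = TRUE)
  checkScalar(duration, "duration", lower = 3 / heart_rate)
  checkScalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  fhCheck(length(image_shape) == 2L && all(image_shape >= 16),
          "invalidParameterError", "image_shape must be c(rows, cols) >= 16")
  checkScalar(noise_sd, "noise_sd", lower = 0)
  checkScalar(blur_sigma, "blur_sigma", lower = 0)
  checkScalar(axis_ratio, "axis_ratio", lower = 0, strict_lower = TRUE)
  structure(list(edv = edv, esv = esv, heart_rate = heart_rate,
                 frame_rate = frame_rate, duration = duration,
                 pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 axis_ratio = axis_ratio, fg = fg, bg = bg,
                 seed = as.integer(seed)),
            class = "CardiacSimParams")
}

# Ellipsoid semi-axes realizing volume V at fixed aspect ratio rho = c/a:
# V = 4/3 pi a^2 c = 4/3 pi rho a^3.
ellipsoidAxes <- function(volume, axis_ratio) {
  a <- (3 * volume / (4 * pi * axis_ratio))^(1 / 3)
  c(a = a, c = axis_ratio * a)
}

renderEllipseFrame <- function(shape, rx_px, ry_px) {
  cy <- (shape[1] + 1) / 2
  cx <- (shape[2] + 1) / 2
  y <- (seq_len(shape[1]) - cy) / ry_px
  x <- (seq_len(shape[2]) - cx) / rx_px
  outer(y^2, x^2, "+") <= 1
}

#' Simulate a paced beating-heart biplane video with ground truth
#'
#' Renders two orthogonal silhouette stacks of a prolate-ellipsoid ventricle
#' whose exact volume follows a raised cosine between ESV and EDV at the
#' pacing rate: the long-axis plane shows an ellipse with semi-axes `c`
#' (horizontal) and `a` (vertical), the short-axis plane a disc of radius
#' `a`. Optical blur and additive Gaussian noise are applied per frame,
#' noise last.
#'
#' @param params a [cardiacSimParams()] object.
#' @return A list with elements
#'   \describe{
#'     \item{video}{a [BiplaneVideo-class].}
#'     \item{truth}{ground truth: per-frame data.frame (`time`, `volume`
#'       mm^3, `a_mm`, `c_mm`, `long_length_mm`, `short_area_mm2`), the
#'       generating `edv`, `esv`, analytic `ef`, `fs`, `fac`, and the
#'       ED/ES frame indices per cycle.}
#'   }
#' @examples
#' sim <- simBeatingHeartVideo(cardiacSimParams(noise_sd = 0, blur_sigma = 0))
#' sim$truth$ef  # (EDV - ESV)/EDV
#' @export
simBeatingHeartVideo <- function(params) {
  fhCheck(inherits(params, "CardiacSimParams"), "invalidParameterError",
          "params must come from cardiacSimParams()")
  p <- params
  n <- floor(p$duration * p$frame_rate)
  t <- (seq_len(n) - 1) / p$frame_rate
  vol <- p$esv + (p$edv - p$esv) * (1 + cos(2 * pi * p$heart_rate * t)) / 2

  ax <- vapply(vol, ellipsoidAxes, numeric(2), axis_ratio = p$axis_ratio)
  a_mm <- ax[1, ]; c_mm <- ax[2, ]

  # rendering bounds at maximal (end-diastolic) size, 2 px safety margin
  amax_px <- max(a_mm) / p$pixel_size
  cmax_px <- max(c_mm) / p$pixel_size
  fhCheck(2 * cmax_px + 4 <= p$image_shape[2] &&
          2 * amax_px + 4 <= p$image_shape[1] &&
          2 * amax_px + 4 <= p$image_shape[2],
          "renderingError",
          "ellipse exceeds image bounds; enlarge image_shape or pixel_size")

  long_stack <- array(0, c(p$image_shape, n))
  short_stack <- array(0, c(p$image_shape, n))
  fhWithSeed(p$seed, {
    for (k in seq_len(n)) {
      a_px <- a_mm[k] / p$pixel_size
      c_px <- c_mm[k] / p$pixel_size
      lf <- ifelse(renderEllipseFrame(p$image_shape, c_px, a_px), p$fg, p$bg)
      sf <- ifelse(renderEllipseFrame(p$image_shape, a_px, a_px), p$fg, p$bg)
      if (p$blur_sigma > 0) {
        lf <- as.matrix(EBImage::gblur(EBImage::Image(lf), p$blur_sigma))
        sf <- as.matrix(EBImage::gblur(EBImage::Image(sf), p$blur_sigma))
      }
      if (p$noise_sd > 0) {
        lf <- lf + rnorm(length(lf), 0, p$noise_sd)
        sf <- sf + rnorm(length(sf), 0, p$noise_sd)
      }
      long_stack[, , k] <- pmin(pmax(lf, 0), 1)
      short_stack[, , k] <- pmin(pmax(sf, 0), 1)
    }
  })

  n_cycles <- floor(p$duration * p$heart_rate)
  period_frames <- p$frame_rate / p$heart_rate
  ed_frames <- pmin(n, round((seq_len(n_cycles) - 1) * period_frames) + 1L)
  es_frames <- pmin(n, round((seq_len(n_cycles) - 0.5) * period_frames) + 1L)

  ratio <- p$esv / p$edv
  truth <- list(
    frames = data.frame(time = t, volume = vol, a_mm = a_mm, c_mm = c_mm,
                        long_length_mm = 2 * c_mm,
                        short_area_mm2 = pi * a_mm^2),
    edv = p$edv, esv = p$esv,
    ef = (p$edv - p$esv) / p$edv,
    fs = 1 - ratio^(1 / 3),
    fac = 1 - ratio^(2 / 3),
    ed_frames = ed_frames, es_frames = es_frames,
    params = p)
  list(video = BiplaneVideo(long_stack, short_stack, p$pixel_size,
                            p$frame_rate),
       truth = truth)
}
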