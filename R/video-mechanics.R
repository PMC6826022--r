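#' Segmentation configuration for ventricle silhouettes
#'
#' @param min_area minimum foreground component area (pixels) below which
#'   segmentation fails.
#' @param closing_radius radius of the disc brush used for morphological
#'   closing (pixels).
#' @return A list of class `SegmentConfig`.
#' @export
segmentConfig <- function(min_area = 50, closing_radius = 2) {
  checkScalar(min_area, "min_area", lower = 1)
  checkScalar(closing_radius, "closing_radius", lower = 0)
  structure(list(min_area = min_area, closing_radius = closing_radius),
            class = "SegmentConfig")
}

#' Segment the ventricle silhouette in one video frame
#'
#' Global (Otsu) thresholding after rescaling intensities to `[0, 1]`,
#' morphological closing, retention of the largest connected foreground
#' component, and hole filling. The result is a single connected region
#' without holes.
#'
#' @param frame numeric intensity matrix.
#' @param config a [segmentConfig()].
#' @return Logical matrix mask.
#' @export
segmentVentricle <- function(frame, config = segmentConfig()) {
  fhCheck(is.matrix(frame) && length(frame) > 0, "invalidParameterError",
          "frame must be a non-empty numeric matrix")
  rng <- range(frame)
  if (diff(rng) <= 0)
    fhStop("segmentationFailureError",
           "frame has no intensity range; nothing to segment")
  x <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x))
  mask <- x > th
  if (config$closing_radius > 0) {
    brush_size <- 2 * round(config$closing_radius) + 1
    mask <- EBImage::closing(mask,
                             EBImage::makeBrush(brush_size, shape = "disc"))
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  if (length(sizes) == 0 || max(sizes) < config$min_area)
    fhStop("segmentationFailureError",
           "no connected component exceeds the minimum area floor")
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask)
  matrix(as.logical(mask), nrow(frame), ncol(frame))
}

#' Geometry of one segmented frame
#'
#' Computes the silhouette area, the maximum caliper extent along the
#' principal axis, the center of mass, and the center-to-boundary distances
#' along equally spaced rays — the quantities feeding biplane volumetry,
#' fractional shortening and radial strain.
#'
#' @param mask logical matrix (non-empty).
#' @param pixel_size mm/pixel (use um/pixel consistently if preferred; the
#'   outputs inherit the unit).
#' @param n_rays number of equally spaced rays from the center of mass.
#' @return A list of class `FrameGeometry`: `area` (pixel_size^2 units),
#'   `long_length` (principal-axis caliper extent), `centroid`
#'   (row, col in pixels), `radii` (length `n_rays`, physical units).
#' @export
frameGeometry <- function(mask, pixel_size, n_rays = 36) {
  fhCheck(is.matrix(mask), "invalidParameterError", "mask must be a matrix")
  mask <- mask > 0
  if (!any(mask)) fhStop("emptyMaskError", "mask has no foreground pixels")
  checkScalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  checkScalar(n_rays, "n_rays", lower = 3)

  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  area <- nrow(idx) * pixel_size^2

  # caliper extent along the first principal axis of the foreground pixels
  centered <- sweep(idx, 2, centroid)
  if (nrow(idx) > 1) {
    ev <- eigen(crossprod(centered) / nrow(idx), symmetric = TRUE)$vectors[, 1]
    proj <- centered %*% ev
    long_length <- (max(proj) - min(proj) + 1) * pixel_size
  } else long_length <- pixel_size

  # march along each ray until first exit from the mask (0.5 px steps)
  angles <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  step <- 0.5
  rmax <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  rs <- seq(0, rmax, by = step)
  radii <- vapply(angles, function(th) {
    rr <- round(centroid[1] + rs * sin(th))
    cc <- round(centroid[2] + rs * cos(th))
    inside <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    inmask <- inside
    inmask[inside] <- mask[cbind(rr[inside], cc[inside])]
    first_out <- which(!inmask)[1]
    if (is.na(first_out)) rs[length(rs)] else rs[max(first_out - 1L, 1L)]
  }, numeric(1)) * pixel_size

  structure(list(area = area, long_length = long_length,
                 centroid = centroid, radii = radii),
            class = "FrameGeometry")
}

#' Biplane area-length ventricular volume
#'
#' The biplane area-length estimate `V = 2/3 * A * L`, with `A` the
#' ventricle area in the transverse (short-axis) plane and `L` the ventricle
#' length in the longitudinal plane. For a prolate ellipsoid
#' (`A = pi a^2`, `L = 2c`) the estimate equals the true volume
#' `4/3 pi a^2 c` exactly.
#'
#' @param area_short short-axis area (mm^2).
#' @param length_long long-axis length (mm).
#' @return Volume (mm^3).
#' @examples
#' biplaneVolume(3, 2)  # 4
#' @export
biplaneVolume <- function(area_short, length_long) {
  fhCheck(all(is.finite(area_short)) && all(is.finite(length_long)) &&
          all(area_short >= 0) && all(length_long >= 0),
          "negativeInputError",
          "area and length must be finite and non-negative")
  (2 / 3) * area_short * length_long
}

#' Detect cardiac cycles on a volume trace
#'
#' Finds one end-systole (local volume minimum) per pacing period with a
#' minimum peak separation of 0.7 periods, then assigns each cycle's
#' end-diastole as the volume maximum between the preceding end-systole (or
#' trace start) and that end-systole; ties break to the earlier frame. The
#' closing frame of each cycle (`end_frame`) is the next cycle's
#' end-diastole, or the post-final-ES maximum when at least 0.3 period of
#' trace remains.
#'
#' @param volume per-frame volume trace.
#' @param frame_rate frames/s.
#' @param pacing_rate pacing rate (beats/s).
#' @return data.frame with `ed_frame`, `es_frame`, `end_frame` (1-based
#'   frame indices; `end_frame` may be `NA` for the final cycle).
#' @export
detectCycles <- function(volume, frame_rate, pacing_rate = 2) {
  checkScalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  checkScalar(pacing_rate, "pacing_rate", lower = 0, strict_lower = TRUE)
  n <- length(volume)
  period_frames <- frame_rate / pacing_rate
  fhCheck(n >= 2 * period_frames, "cycleDetectionError",
          "trace must span at least two pacing periods")
  if (diff(range(volume)) <= 0)
    fhStop("cycleDetectionError", "volume trace has no oscillation")

  min_sep <- max(1L, round(0.7 * period_frames))
  # peakpat admits flat-topped extrema (pixel quantization produces plateaus)
  pk <- pracma::findpeaks(-volume, minpeakdistance = min_sep,
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk))
    fhStop("cycleDetectionError", "no end-systolic minima found")
  es <- sort(pk[, 2])
  expected <- floor(n / period_frames)
  if (abs(length(es) - expected) > 1)
    fhStop("cycleDetectionError",
           sprintf("found %d cycles where about %d were expected",
                   length(es), expected))

  ed <- integer(length(es))
  prev <- 1L
  for (j in seq_along(es)) {
    seg <- prev:es[j]
    ed[j] <- seg[which.max(volume[seg])]
    prev <- es[j]
  }
  end_frame <- c(ed[-1], NA_integer_)
  tail_len <- n - es[length(es)]
  if (tail_len >= 0.3 * period_frames) {
    seg <- (es[length(es)] + 1L):n
    end_frame[length(es)] <- seg[which.max(volume[seg])]
  }
  data.frame(ed_frame = ed, es_frame = es, end_frame = end_frame)
}

#' Per-cycle systolic indices
#'
#' Ejection fraction `EF = (EDV - ESV)/EDV`, fractional shortening
#' `FS = (L_d - L_s)/L_d` from long-axis lengths, and fractional area change
#' `FAC = (EDA - ESA)/EDA` from short-axis areas.
#'
#' @param edv,esv end-diastolic and end-systolic volumes (mm^3).
#' @param l_d,l_s end-diastolic and end-systolic long-axis lengths (mm);
#'   optional.
#' @param eda,esa end-diastolic and end-systolic short-axis areas (mm^2);
#'   optional.
#' @return A list with `ef`, and `fs`/`fac` when their inputs are given.
#' @examples
#' cycleIndices(4, 2)$ef           # 0.5
#' cycleIndices(4, 2, 2, 1.5)$fs   # 0.25
#' @export
cycleIndices <- function(edv, esv, l_d = NULL, l_s = NULL,
                         eda = NULL, esa = NULL) {
  fhCheck(isScalarNum(edv) && isScalarNum(esv) && esv >= 0 && edv >= esv,
          "invalidParameterError", "need EDV >= ESV >= 0")
  fhCheck(edv > 0, "divisionByZeroError", "EDV is zero")
  out <- list(ef = (edv - esv) / edv)
  if (!is.null(l_d)) {
    fhCheck(l_d > 0, "divisionByZeroError", "end-diastolic length is zero")
    fhCheck(l_d >= l_s && l_s >= 0, "invalidParameterError",
            "need L_d >= L_s >= 0")
    out$fs <- (l_d - l_s) / l_d
  }
  if (!is.null(eda)) {
    fhCheck(eda > 0, "divisionByZeroError", "end-diastolic area is zero")
    fhCheck(eda >= esa && esa >= 0, "invalidParameterError",
            "need EDA >= ESA >= 0")
    out$fac <- (eda - esa) / eda
  }
  out
}

#' Radial strain and strain-rate velocity series
#'
#' Radial strain is the fractional change of the mean center-to-boundary
#' radius relative to its end-diastolic value:
#' `strain(t) = (rbar(t) - rbar_ED)/rbar_ED`. The velocity is the centered
#' finite difference of the (optionally Savitzky-Golay smoothed) strain;
#' the extrema are reported as the maximal contraction (most negative) and
#' relaxation (most positive) velocities.
#'
#' @param radii matrix of per-frame ray lengths (frames x rays), or a vector
#'   of per-frame mean radii.
#' @param frame_rate frames/s.
#' @param ref_frame end-diastolic reference frame; defaults to the frame of
#'   maximal mean radius.
#' @param window odd smoothing window length (frames); 1 disables smoothing.
#' @param order polynomial order of the smoother.
#' @return A list of class `StrainVelocitySeries`: `time`, `strain`,
#'   `velocity`, `max_contraction_velocity`, `max_relaxation_velocity`.
#' @export
strainVelocitySeries <- function(radii, frame_rate, ref_frame = NULL,
                                 window = 7, order = 2) {
  rbar <- if (is.matrix(radii)) rowMeans(radii) else as.numeric(radii)
  checkScalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  n <- length(rbar)
  fhCheck(n >= max(window, 3) + 2, "insufficientFramesError",
          "too few frames for strain/velocity analysis")
  if (is.null(ref_frame)) ref_frame <- which.max(rbar)
  fhCheck(rbar[ref_frame] > 0, "invalidParameterError",
          "reference mean radius must be positive")
  strain <- (rbar - rbar[ref_frame]) / rbar[ref_frame]
  smoothed <- if (window > 1)
    signal::sgolayfilt(strain, p = order, n = window) else strain
  velocity <- pracma::gradient(smoothed, 1 / frame_rate)
  structure(list(time = (seq_len(n) - 1) / frame_rate,
                 strain = smoothed, velocity = velocity,
                 max_contraction_velocity = min(velocity),
                 max_relaxation_velocity = max(velocity)),
            class = "StrainVelocitySeries")
}

#' Velocity-strain loop area
#'
#' Area of the closed polygon traced frame-to-frame by (strain, velocity)
#' over one cardiac cycle, by the shoelace formula; the absolute value is
#' reported, so the traversal orientation is irrelevant. For harmonic strain
#' of amplitude `D` at angular rate `w` the loop is an ellipse of area
#' `pi * w * D^2`.
#'
#' @param strain,velocity cycle-ordered vertex coordinates (strain,
#'   strain/s).
#' @param closure_tol maximal allowed strain gap between the first and last
#'   vertex before the loop is declared open.
#' @return Loop area (strain^2/s).
#' @export
velocityStrainLoop <- function(strain, velocity, closure_tol = 0.05) {
  fhCheck(length(strain) == length(velocity) && length(strain) >= 3,
          "invalidParameterError",
          "need matched strain/velocity vectors of length >= 3")
  if (abs(strain[1] - strain[length(strain)]) > closure_tol)
    fhStop("openLoopError",
           "cycle endpoints differ by more than the closure tolerance")
  x <- strain; y <- velocity
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Full beating-heart video analysis
#'
#' Runs the complete ex vivo chain on a biplane video: per-frame
#' segmentation of both planes, frame geometry, biplane volumes, cycle
#' detection on the volume trace, per-cycle EF/FS/FAC, radial strain and
#' strain-rate extrema from the short-axis silhouette, and velocity-strain
#' loop areas; at least three complete cycles are analyzed and averaged.
#'
#' @param video a [BiplaneVideo-class].
#' @param pacing_rate pacing rate (beats/s).
#' @param seg_config a [segmentConfig()].
#' @param n_rays rays for radial strain.
#' @param smooth_window,smooth_order strain smoothing settings
#'   (see [strainVelocitySeries()]).
#' @param loop_tol loop closure tolerance (strain units).
#' @return A [HeartFunctionSummary-class].
#' @export
summarizeHeart <- function(video, pacing_rate = 2,
                           seg_config = segmentConfig(), n_rays = 36,
                           smooth_window = 7, smooth_order = 2,
                           loop_tol = 0.05) {
  fhCheck(is(video, "BiplaneVideo"), "invalidParameterError",
          "video must be a BiplaneVideo")
  n <- nFrames(video)
  ps <- pixelSize(video)
  fr <- frameRate(video)

  long_len <- numeric(n)
  short_area <- numeric(n)
  mean_radius <- numeric(n)
  for (k in seq_len(n)) {
    gl <- tryCatch(
      frameGeometry(segmentVentricle(planeLong(video)[, , k], seg_config),
                    ps, n_rays),
      fishheartError = function(e)
        fhStop("segmentationFailureError",
               sprintf("long-axis plane, frame %d: %s", k,
                       conditionMessage(e))))
    gs <- tryCatch(
      frameGeometry(segmentVentricle(planeShort(video)[, , k], seg_config),
                    ps, n_rays),
      fishheartError = function(e)
        fhStop("segmentationFailureError",
               sprintf("short-axis plane, frame %d: %s", k,
                       conditionMessage(e))))
    long_len[k] <- gl$long_length
    short_area[k] <- gs$area
    mean_radius[k] <- mean(gs$radii)
  }

  volume <- biplaneVolume(short_area, long_len)
  cyc <- detectCycles(volume, fr, pacing_rate)
  complete <- !is.na(cyc$end_frame)
  cyc <- cyc[complete, , drop = FALSE]
  fhCheck(nrow(cyc) >= 3, "cycleDetectionError",
          "fewer than 3 complete cardiac cycles detected")

  rows <- lapply(seq_len(nrow(cyc)), function(j) {
    ed <- cyc$ed_frame[j]; es <- cyc$es_frame[j]; fin <- cyc$end_frame[j]
    idx <- cycleIndices(volume[ed], min(volume[ed], volume[es]),
                        l_d = long_len[ed],
                        l_s = min(long_len[ed], long_len[es]),
                        eda = short_area[ed],
                        esa = min(short_area[ed], short_area[es]))
    seg <- ed:fin
    sv <- strainVelocitySeries(mean_radius[seg], fr, ref_frame = 1L,
                               window = min(smooth_window,
                                            2 * floor((length(seg) - 2) / 2) - 1),
                               order = smooth_order)
    loop <- tryCatch(
      velocityStrainLoop(sv$strain, sv$velocity, closure_tol = loop_tol),
      openLoopError = function(e) NA_real_)
    data.frame(cycle = j, ed_frame = ed, es_frame = es,
               edv = volume[ed], esv = min(volume[ed], volume[es]),
               ef = idx$ef, fs = idx$fs, fac = idx$fac,
               max_contraction_velocity = sv$max_contraction_velocity,
               max_relaxation_velocity = sv$max_relaxation_velocity,
               loop_area = loop)
  })
  cycles <- do.call(rbind, rows)
  cols <- c("edv", "esv", "ef", "fs", "fac", "max_contraction_velocity",
            "max_relaxation_velocity", "loop_area")
  means <- vapply(cols, function(cl) mean(cycles[[cl]], na.rm = TRUE),
                  numeric(1))
  new("HeartFunctionSummary", cycles = cycles, means = means)
}
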