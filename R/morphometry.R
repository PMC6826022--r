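# Otsu threshold on an arbitrary pixel vector, after rescaling to [0, 1].
otsuThreshold <- function(pix) {
  rng <- range(pix)
  fhCheck(diff(rng) > 0, "invalidParameterError",
          "cannot threshold an image with no intensity range")
  x <- (pix - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(x, nrow = 1)))
  th * diff(rng) + rng[1]
}

#' Ventricular surface area to body weight index (VSA/BW)
#'
#' The largest projection area of the dissected ventricle (mm^2) divided by
#' body weight (g) — the standard heart-size index for adult zebrafish,
#' whose small hearts preclude direct mass measurement.
#'
#' @param mask logical/binary matrix outlining the largest ventricle
#'   projection.
#' @param pixel_size mm/pixel.
#' @param body_weight body weight (g), > 0.
#' @return A list: `vsa` (mm^2), `vsa_bw` (mm^2/g).
#' @examples
#' m <- matrix(1, 100, 100)          # 1 mm^2 at 0.01 mm/px
#' normalizedVentricleSize(m, 0.01, 0.5)$vsa_bw  # 2
#' @export
normalizedVentricleSize <- function(mask, pixel_size, body_weight) {
  fhCheck(is.matrix(mask), "invalidParameterError", "mask must be a matrix")
  fhCheck(any(mask > 0), "emptyMaskError", "mask has no foreground pixels")
  checkScalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  fhCheck(isScalarNum(body_weight) && body_weight > 0, "zeroWeightError",
          "body weight must be positive")
  vsa <- sum(mask > 0) * pixel_size^2
  list(vsa = vsa, vsa_bw = vsa / body_weight)
}

#' Foreground area fraction within a region of interest
#'
#' Fraction of ROI pixels above threshold. Binary input (values only 0/1)
#' is used directly; otherwise an Otsu threshold is computed from the ROI
#' pixels, making the fraction invariant to intensity rescaling. Covers
#' trabecular-muscle density on histology and intact-myofibril fraction on
#' TEM fields.
#'
#' @param image numeric matrix.
#' @param roi logical matrix of the same shape, or `NULL` for the whole
#'   image.
#' @param threshold fixed threshold; `NULL` selects automatic (Otsu).
#' @return A list: `fraction`, `n_foreground`, `n_roi`, `threshold`.
#' @export
areaFraction <- function(image, roi = NULL, threshold = NULL) {
  fhCheck(is.matrix(image), "invalidParameterError",
          "image must be a matrix")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  fhCheck(all(dim(roi) == dim(image)), "invalidParameterError",
          "roi must match the image shape")
  roi <- roi > 0
  fhCheck(any(roi), "emptyRoiError", "ROI has no pixels")
  pix <- image[roi]
  vals <- unique(pix)
  if (is.null(threshold)) {
    threshold <- if (all(vals %in% c(0, 1))) 0.5 else otsuThreshold(pix)
  }
  fg <- pix > threshold
  list(fraction = mean(fg), n_foreground = sum(fg), n_roi = length(pix),
       threshold = threshold)
}

#' Percentage of positive nuclei
#'
#' Detects nuclei on the nuclear-stain channel as connected components
#' above threshold with areas inside `[min_area, max_area]` (excluding
#' debris and merged clumps), then calls a nucleus positive when its mean
#' intensity in the positive channel exceeds `positive_threshold`. Covers
#' TUNEL- and PCNA-positive percentages.
#'
#' @param total nuclear-stain channel (numeric matrix).
#' @param positive positive-label channel, same shape.
#' @param min_area,max_area admissible nucleus area bounds (pixels).
#' @param detect_threshold nuclear-channel threshold; `NULL` selects Otsu.
#' @param positive_threshold mean-intensity threshold in the positive
#'   channel.
#' @return A list: `percent` (0-100), `n_total`, `n_positive`,
#'   `n_excluded` (components outside the area bounds).
#' @export
nucleiFraction <- function(total, positive, min_area = 20, max_area = 2000,
                           detect_threshold = NULL,
                           positive_threshold = 0.5) {
  fhCheck(is.matrix(total) && is.matrix(positive) &&
          all(dim(total) == dim(positive)), "invalidParameterError",
          "channels must be matrices of the same shape")
  if (is.null(detect_threshold)) detect_threshold <- otsuThreshold(total)
  lab <- EBImage::bwlabel(total > detect_threshold)
  lab <- as.integer(lab)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area & sizes <= max_area)
  n_excluded <- sum(sizes > 0) - length(keep)
  if (length(keep) == 0)
    fhStop("noNucleiError", "no nuclei detected within the area bounds")
  means <- vapply(keep, function(l) mean(positive[lab == l]), numeric(1))
  n_pos <- sum(means > positive_threshold)
  list(percent = 100 * n_pos / length(keep), n_total = length(keep),
       n_positive = n_pos, n_excluded = n_excluded)
}

#' Per-cell areas from labeled masks
#'
#' Pixel counts per label converted to physical areas — the outlined single
#' cardiomyocyte area measurement.
#'
#' @param labels integer matrix of cell labels (0 = background).
#' @param pixel_size um/pixel.
#' @return A list: `areas` (um^2, one per label), `mean`, `sd`, `n`.
#' @examples
#' lab <- matrix(0L, 40, 40); lab[10:29, 10:29] <- 1L
#' cellAreas(lab, 1)$areas  # 400
#' @export
cellAreas <- function(labels, pixel_size = 1) {
  fhCheck(is.matrix(labels), "invalidParameterError",
          "labels must be a matrix")
  checkScalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  counts <- tabulate(as.integer(labels[labels > 0]))
  counts <- counts[counts > 0]
  if (length(counts) == 0)
    fhStop("noCellsError", "no labeled cells in the mask")
  areas <- counts * pixel_size^2
  list(areas = areas, mean = mean(areas),
       sd = if (length(areas) > 1) sd(areas) else 0, n = length(areas))
}
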