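#' Simulate a binary image with an exact foreground fraction
#'
#' Scatters exactly `round(fraction * rows * cols)` foreground pixels at
#' random positions, so the ground-truth area fraction is exact to the
#' pixel-rounding limit.
#'
#' @param shape integer `c(rows, cols)`.
#' @param fraction target foreground fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return A list with `image` (0/1 matrix) and `truth`
#'   (`fraction` actually realized, `n_foreground`).
#' @export
simAreaFractionImage <- function(shape = c(100L, 100L), fraction = 0.25,
                                 seed = 1L) {
  fhCheck(length(shape) == 2L && all(shape >= 1), "invalidParameterError",
          "shape must be c(rows, cols) >= 1")
  checkScalar(fraction, "fraction", lower = 0, upper = 1)
  npix <- prod(shape)
  k <- round(fraction * npix)
  img <- matrix(0L, shape[1], shape[2])
  if (k > 0)
    img[fhWithSeed(seed, sample.int(npix, k))] <- 1L
  list(image = img,
       truth = list(fraction = k / npix, n_foreground = k))
}

# place n non-overlapping disc centers with minimum separation on a grid
placeCenters <- function(shape, n, radius, min_sep, seed) {
  margin <- radius + 1
  fhWithSeed(seed, {
    centers <- matrix(NA_real_, n, 2)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 5000L * max(n, 1L)
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        fhStop("infeasiblePackingError",
               "could not place all objects without overlap")
      cand <- c(stats::runif(1, margin, shape[1] - margin),
                stats::runif(1, margin, shape[2] - margin))
      if (placed == 0L ||
          min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                 2, cand)^2))) >= min_sep) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    centers
  })
}

stampDisc <- function(img, center, radius, value) {
  rr <- max(1, floor(center[1] - radius)):min(nrow(img), ceiling(center[1] + radius))
  cc <- max(1, floor(center[2] - radius)):min(ncol(img), ceiling(center[2] + radius))
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  sub <- img[rr, cc]
  sub[d2 <= radius^2] <- value
  img[rr, cc] <- sub
  img
}

#' Simulate a two-channel nuclei image with a known positive fraction
#'
#' Places `n` non-overlapping disc nuclei on a nuclear-stain channel and
#' marks the first `k` of them as positive in a second channel, emulating a
#' TUNEL- or PCNA-stained section with a known positive-nuclei percentage.
#'
#' @param shape integer `c(rows, cols)`.
#' @param n total nuclei; `k` of them positive (`0 <= k <= n`).
#' @param k positive nuclei count.
#' @param radius nuclear radius (pixels).
#' @param seed integer seed.
#' @return A list with `total` and `positive` intensity matrices on
#'   `[0, 1]`, plus `truth` (`n`, `k`, `percent_positive`, centers).
#' @export
simNucleiImage <- function(shape = c(256L, 256L), n = 100L, k = 20L,
                           radius = 4, seed = 1L) {
  fhCheck(length(shape) == 2L && all(shape >= 4 * radius),
          "invalidParameterError", "shape too small for the nucleus radius")
  checkScalar(n, "n", lower = 1)
  checkScalar(k, "k", lower = 0, upper = n)
  checkScalar(radius, "radius", lower = 1)
  n <- as.integer(n); k <- as.integer(k)
  centers <- placeCenters(shape, n, radius, min_sep = 2 * radius + 3,
                          seed = seed)
  total <- matrix(0.05, shape[1], shape[2])
  positive <- matrix(0.02, shape[1], shape[2])
  for (i in seq_len(n)) {
    total <- stampDisc(total, centers[i, ], radius, 0.9)
    if (i <= k)
      positive <- stampDisc(positive, centers[i, ], radius, 0.85)
  }
  list(total = total, positive = positive,
       truth = list(n = n, k = k, percent_positive = 100 * k / n,
                    centers = centers))
}

#' Simulate labeled cell masks with known pixel areas
#'
#' Places `n` non-overlapping square cells (labels 1..n) on a background of
#' zeros, emulating manually outlined cardiomyocyte masks.
#'
#' @param shape integer `c(rows, cols)`.
#' @param n number of cells.
#' @param side square side length in pixels, recycled across cells.
#' @param seed integer seed.
#' @return A list with `labels` (integer matrix) and `truth`
#'   (`areas_px`, pixel count per label).
#' @export
simCellMasks <- function(shape = c(256L, 256L), n = 5L, side = 20L,
                         seed = 1L) {
  checkScalar(n, "n", lower = 1)
  n <- as.integer(n)
  side <- rep_len(as.integer(side), n)
  fhCheck(all(side >= 1) && all(max(side) * 2 < shape),
          "invalidParameterError", "cell side too large for image shape")
  half <- max(side) / 2
  centers <- placeCenters(shape, n, radius = half,
                          min_sep = sqrt(2) * max(side) + 2, seed = seed)
  labels <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(n)) {
    r0 <- round(centers[i, 1] - side[i] / 2)
    c0 <- round(centers[i, 2] - side[i] / 2)
    labels[r0:(r0 + side[i] - 1L), c0:(c0 + side[i] - 1L)] <- i
  }
  list(labels = labels, truth = list(areas_px = side^2))
}
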