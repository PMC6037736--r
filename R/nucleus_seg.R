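#' @include AllClasses.R utils.R
NULL

#' Locally adaptive threshold
#'
#' Foreground mask from a locally estimated threshold: the local mean
#' over a `window x window` box (plus `k` local standard deviations) is
#' subtracted, and the residual image is split by Otsu's criterion on its
#' own histogram. Because every step is linear in the image values, the
#' mask is invariant to global multiplicative rescaling, and the local
#' mean removes slow illumination gradients that defeat a global
#' threshold.
#'
#' @param image numeric intensity matrix.
#' @param window odd box size (pixels) for the local statistics.
#' @param k weight of the local standard deviation added to the local
#'   mean before residual thresholding.
#' @param noise_floor significance floor in robust noise units: the
#'   threshold never falls below `noise_floor` times a robust pixel-noise
#'   scale (median absolute deviation of adjacent-pixel differences,
#'   insensitive to smooth structure), so pure counting noise yields an
#'   empty mask instead of speckle.
#' @return logical matrix; a constant image yields an all-background
#'   mask with a warning.
#' @export
adaptiveThreshold <- function(image, window = 31L, k = 0, noise_floor = 5) {
  stopIfNot(window >= 3L && window %% 2L == 1L, "window must be odd and >= 3")
  if (diff(range(image)) == 0) {
    warning("constant image: no foreground found")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  mu <- localBoxMean(image, window)
  resid <- image - mu
  if (k != 0) {
    m2 <- localBoxMean(image^2, window)
    resid <- resid - k * sqrt(pmax(m2 - mu^2, 0))
  }
  rng <- range(resid)
  thr <- EBImage::otsu(EBImage::Image(resid), range = rng, levels = 256L)
  noise_sigma <- stats::mad(diff(resid)) / sqrt(2)
  thr <- max(thr, noise_floor * noise_sigma)
  resid > thr
}

#' Morphological cleanup of a binary mask
#'
#' Erosion by a 3 x 3 square kernel (breaking thin bridges between
#' touching nuclei), dilation by a radius-2 disc, then removal of
#' connected components with area below 20 pixels (strict: a 19-pixel
#' object is rejected, a 20-pixel object is kept).
#'
#' @param mask logical or 0/1 matrix.
#' @param min_area minimum component area kept, pixels.
#' @return logical matrix.
#' @export
morphologicalClean <- function(mask, min_area = 20L) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- EBImage::erode(m, EBImage::makeBrush(3L, shape = "box"))
  m <- EBImage::dilate(m, EBImage::makeBrush(5L, shape = "disc"))
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(areas < min_area)
    if (length(small)) m[lab %in% small] <- 0
  }
  matrix(m > 0, nrow(mask), ncol(mask))
}

relabelSequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(match(lab, ids, nomatch = 0L) , nrow(lab), ncol(lab))
  storage.mode(out) <- "integer"
  out
}

#' Watershed labelling of a cleaned mask
#'
#' Splits touching nuclei by marker-controlled watershed on the Euclidean
#' distance transform: each regional maximum of the distance map (one per
#' roughly circular nucleus) seeds a catchment basin of the inverted map.
#' Shallow maxima within `tolerance` of a deeper neighbour are merged to
#' prevent over-segmentation from pixel-level noise. Components smaller
#' than `min_area` after splitting are removed and labels renumbered
#' 1..N.
#'
#' @param mask logical or 0/1 matrix (output of [morphologicalClean()]).
#' @param tolerance depth tolerance for merging shallow basins, pixels.
#' @param min_area minimum labelled area kept, pixels.
#' @return integer label matrix (0 = background).
#' @export
watershedLabels <- function(mask, tolerance = 1, min_area = 20L) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(m)
  lab <- EBImage::watershed(d, tolerance = tolerance, ext = 1L)
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(areas < min_area)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  relabelSequential(lab)
}

#' Segment nuclei from a pooled intensity image
#'
#' Full segmentation chain: background subtraction, Gaussian smoothing,
#' locally adaptive thresholding, morphological cleanup with the <20 px
#' area rule, and distance-transform watershed splitting of touching
#' nuclei. The chain is deterministic.
#'
#' @param image numeric intensity matrix (e.g.
#'   `intensityImage(pooled)`).
#' @param background scalar or matrix background level subtracted first.
#' @param window,k adaptive threshold parameters, see
#'   [adaptiveThreshold()].
#' @param smooth_sigma Gaussian smoothing before thresholding, pixels.
#' @param min_area minimum nucleus area, pixels.
#' @param tolerance watershed basin-merging tolerance, pixels.
#' @return integer label matrix (0 = background, 1..N nuclei).
#' @export
segmentNuclei <- function(image, background = 0, window = 31L, k = 0,
                          smooth_sigma = 1, min_area = 20L, tolerance = 1) {
  if (is.matrix(background))
    stopIfNot(identical(dim(background), dim(image)),
              "background image must match the image shape")
  img <- pmax(image - background, 0)
  img <- gaussianSmooth(img, smooth_sigma)
  mask <- adaptiveThreshold(img, window = window, k = k)
  if (!any(mask)) return(matrix(0L, nrow(image), ncol(image)))
  mask <- morphologicalClean(mask, min_area = min_area)
  watershedLabels(mask, tolerance = tolerance, min_area = min_area)
}

#' Per-label areas and centroids
#'
#' @param labels integer label matrix.
#' @return data.frame with `label`, `area` (pixels), `centroid_row`,
#'   `centroid_col`.
#' @export
labelStats <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  rows <- row(labels); cols <- col(labels)
  data.frame(
    label = ids,
    area = vapply(ids, function(i) sum(labels == i), integer(1)),
    centroid_row = vapply(ids, function(i) mean(rows[labels == i]), numeric(1)),
    centroid_col = vapply(ids, function(i) mean(cols[labels == i]), numeric(1))
  )
}
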