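#' @include decay_fit.R
NULL

#' Pixel-wise FRET fraction and mean-lifetime maps
#'
#' Fits the fixed-lifetime two-component donor model pixel by pixel.
#' Decay histograms are first box-summed over a 3 x 3 neighbourhood
#' (photon-conserving spatial averaging); only pixels whose summed
#' histogram holds strictly more than `photon_threshold` photons are
#' fitted, and only pixels inside a labelled nucleus are considered.
#' Per-nucleus values are the plain averages of the qualifying pixels'
#' fits; a nucleus with no qualifying pixel is flagged missing.
#'
#' @param pooled a [PooledFLIMImage-class].
#' @param labels integer label matrix on the same grid.
#' @param irf an [IRFProfile-class] or `NULL` for a delta IRF.
#' @param tau_long_ps,tau_short_ps fixed lifetime components, ps.
#' @param photon_threshold minimum photons (strict >) per box-summed
#'   pixel histogram.
#' @param box box side for spatial averaging, pixels.
#' @param background `"free"` or `"none"`, see [fitGlobalBiexp()].
#' @return list with `pixel_f` and `pixel_tau` (matrices, `NA` outside
#'   fitted pixels) and `nuclei` (data.frame: `label`, `n_pixels_fit`,
#'   `fret_fraction`, `tau_mean_iw_ps`, `missing`).
#' @export
pixelFractionMap <- function(pooled, labels, irf = NULL,
                             tau_long_ps = 2460, tau_short_ps = 770,
                             photon_threshold = 300, box = 3L,
                             background = c("free", "none")) {
  background <- match.arg(background)
  d <- dim(pooled@counts)
  stopIfNot(identical(dim(labels), d[1:2]),
            "labels must share the pooled image grid")
  H <- d[1]; W <- d[2]; B <- d[3]
  sm <- array(0, dim = d)
  for (b in seq_len(B))
    sm[, , b] <- localBoxSum(pooled@counts[, , b], box)
  dim(sm) <- c(H * W, B)
  tot <- rowSums(sm)
  qual <- tot > photon_threshold & as.vector(labels) > 0
  kern <- irfKernel(irf, pooled@period_ns, B)
  comp <- function(tau) {
    dd <- singleDecayBins(tau, pooled@period_ns, B)
    if (!is.null(kern)) dd <- circConvolve(dd, kern)
    dd
  }
  d_long <- comp(tau_long_ps); d_short <- comp(tau_short_ps)
  free_bg <- background == "free"
  pixel_f <- matrix(NA_real_, H, W)
  pixel_tau <- matrix(NA_real_, H, W)
  for (i in which(qual)) {
    fit <- fitWeightsOne(sm[i, ], d_short, d_long, free_bg, B)
    wl <- 1 - fit$ws - fit$wb
    ws_rel <- if (fit$ws + wl > 0) fit$ws / (fit$ws + wl) else 0
    f <- photonWeightToPop(ws_rel, tau_short_ps, tau_long_ps)
    pixel_f[i] <- f
    pixel_tau[i] <- intensityWeightedMeanLifetime(
      c(1 - f, f), c(tau_long_ps, tau_short_ps))
  }
  ids <- sort(unique(labels[labels > 0]))
  nuc <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id & !is.na(pixel_f)
    n <- sum(sel)
    data.frame(label = id, n_pixels_fit = n,
               fret_fraction = if (n) mean(pixel_f[sel]) else NA_real_,
               tau_mean_iw_ps = if (n) mean(pixel_tau[sel]) else NA_real_,
               missing = n == 0L)
  }))
  if (!is.null(nuc) && any(nuc$missing))
    message(sum(nuc$missing),
            " nuclei have no pixel above the photon threshold")
  list(pixel_f = pixel_f, pixel_tau = pixel_tau,
       nuclei = if (is.null(nuc))
         data.frame(label = integer(0), n_pixels_fit = integer(0),
                    fret_fraction = numeric(0), tau_mean_iw_ps = numeric(0),
                    missing = logical(0))
       else nuc)
}
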