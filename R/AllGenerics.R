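#' @include AllClasses.R
NULL

#' Number of photons in an object
#'
#' @param x a [DecayHistogram-class], [PhotonEventStream-class] or
#'   [PooledFLIMImage-class].
#' @return total photon count (for background-corrected histograms, the
#'   sum of corrected counts).
#' @export
setGeneric("nPhotons", function(x) standardGeneric("nPhotons"))

#' @rdname nPhotons
#' @export
setMethod("nPhotons", "DecayHistogram", function(x) sum(x@counts))

#' @rdname nPhotons
#' @export
setMethod("nPhotons", "PhotonEventStream", function(x) nrow(x@events))

#' @rdname nPhotons
#' @export
setMethod("nPhotons", "PooledFLIMImage", function(x) sum(x@counts))

#' Integrated intensity image
#'
#' Photon counts per pixel: summed over all frames (and optionally a
#' single frame) for an event stream, or over micro-time bins for a
#' pooled FLIM image.
#'
#' @param x a [PhotonEventStream-class] or [PooledFLIMImage-class].
#' @param frame optional 0-based frame index; default all frames.
#' @return numeric `height x width` matrix of counts.
#' @export
setGeneric("intensityImage", function(x, frame = NULL)
  standardGeneric("intensityImage"))

#' @rdname intensityImage
#' @export
setMethod("intensityImage", "PhotonEventStream", function(x, frame = NULL) {
  ev <- x@events
  if (!is.null(frame)) ev <- ev[ev$frame == frame, , drop = FALSE]
  img <- matrix(0, x@height, x@width)
  if (nrow(ev)) {
    idx <- ev$row + 1L + ev$col * x@height
    tab <- tabulate(idx, nbins = x@height * x@width)
    img[] <- tab
  }
  img
})

#' @rdname intensityImage
#' @export
setMethod("intensityImage", "PooledFLIMImage", function(x, frame = NULL) {
  apply(x@counts, c(1, 2), sum)
})

#' Event table accessor
#' @param x a [PhotonEventStream-class].
#' @return the events data.frame (`frame`, `row`, `col`, `tbin`, 0-based).
#' @export
eventTable <- function(x) {
  stopifnot(is(x, "PhotonEventStream"))
  x@events
}

#' Nucleus ground-truth accessor
#' @param x a [Scene-class].
#' @return the nuclei truth data.frame.
#' @export
sceneNuclei <- function(x) {
  stopifnot(is(x, "Scene"))
  x@nuclei
}

#' Decay histogram accessors
#' @param x a [DecayHistogram-class].
#' @return `decayCounts`: per-bin counts; `binWidth`: bin width in ns.
#' @export
decayCounts <- function(x) {
  stopifnot(is(x, "DecayHistogram"))
  x@counts
}

#' @rdname decayCounts
#' @export
binWidth <- function(x) {
  stopifnot(is(x, "DecayHistogram"))
  x@period_ns / length(x@counts)
}

#' Alignment report accessor
#' @param x an [AlignmentReport-class].
#' @return per-frame data.frame (`frame`, `d_row`, `d_col`, `score`,
#'   `accepted`).
#' @export
alignmentFrames <- function(x) {
  stopifnot(is(x, "AlignmentReport"))
  x@frames
}

#' Global-fit accessors
#' @param x a [BiExpGlobalFit-class].
#' @return `fretFractions`: per-segment FRETing population fractions;
#'   `meanLifetimes`: per-segment intensity-weighted mean lifetimes (ps);
#'   `shortLifetime`: the shared short lifetime component (ps).
#' @export
fretFractions <- function(x) {
  stopifnot(is(x, "BiExpGlobalFit"))
  x@fractions
}

#' @rdname fretFractions
#' @export
meanLifetimes <- function(x) {
  stopifnot(is(x, "BiExpGlobalFit"))
  x@tau_mean_iw_ps
}

#' @rdname fretFractions
#' @export
shortLifetime <- function(x) {
  stopifnot(is(x, "BiExpGlobalFit"))
  x@tau_short_ps
}

#' Calibration table accessor
#' @param x a [CalibrationTable-class].
#' @return data.frame with `concentration_uM`, `nonfret_fraction`.
#' @export
calibrationData <- function(x) {
  stopifnot(is(x, "CalibrationTable"))
  x@table
}

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d x %d px, %d frames @ %.2f Hz, %d bins / %.3g ns\n",
              object@height, object@width, object@n_frames,
              object@frame_rate_hz, object@n_bins, object@period_ns))
  cat(sprintf("  %d nuclei, background %.3g photons/px/frame, bleed %.3g/uM\n",
              nrow(object@nuclei), object@background_rate, object@bleed_coeff))
})

setMethod("show", "PhotonEventStream", function(object) {
  cat(sprintf("PhotonEventStream: %d events, %d x %d px, %d bins / %.3g ns, %.2f Hz\n",
              nrow(object@events), object@height, object@width,
              object@n_bins, object@period_ns, object@frame_rate_hz))
  nf <- if (nrow(object@events)) max(object@events$frame) + 1L else 0L
  cat(sprintf("  frames spanned: %d\n", nf))
})

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins, %.3g ns period, %.4g photons%s\n",
              length(object@counts), object@period_ns, sum(object@counts),
              if (length(object@variance)) " (background-corrected)" else ""))
})

setMethod("show", "AlignmentReport", function(object) {
  fr <- object@frames
  cat(sprintf("AlignmentReport: %d frames, %d accepted (threshold %.2f, search +/-%d px)\n",
              nrow(fr), sum(fr$accepted), object@threshold, object@search_range))
})

setMethod("show", "PooledFLIMImage", function(object) {
  d <- dim(object@counts)
  cat(sprintf("PooledFLIMImage: %d x %d px, %d bins, %d frames used, %.4g photons (%d dropped out-of-bounds)\n",
              d[1], d[2], d[3], object@n_frames_used, sum(object@counts),
              object@n_dropped_oob))
})

setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf("CalibrationTable: %d points, C in [%g, %g] uM, tau = %g/%g ps, bleed %.3g/uM\n",
              nrow(object@table), min(object@table$concentration_uM),
              max(object@table$concentration_uM), object@tau_long_ps,
              object@tau_short_ps, object@bleed_coeff))
})

setMethod("show", "SingleExpFit", function(object) {
  cat(sprintf("SingleExpFit: tau = %.1f ps, %g photons, chi2_red = %.3g%s\n",
              object@tau_ps, object@n_photons, object@fit_quality,
              if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "BiExpGlobalFit", function(object) {
  cat(sprintf("BiExpGlobalFit: %d segments, tau = %g/%g ps (short %s)\n",
              length(object@fractions), object@tau_long_ps, object@tau_short_ps,
              if (object@tau_short_fitted) "fitted globally" else "fixed"))
  cat(sprintf("  f: median %.3f [%.3f, %.3f]\n",
              median(object@fractions), min(object@fractions),
              max(object@fractions)))
})
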