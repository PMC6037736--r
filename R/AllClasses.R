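#' @include utils.R
NULL

#' Synthetic acquisition scene
#'
#' Ground-truth description of a synthetic endomicroscopy field of view:
#' image geometry, acquisition timing, TCSPC binning, nucleus truth table,
#' uniform background rate and the linear doxorubicin bleed-through
#' coefficient. Scenes are created with [makeScene()].
#'
#' @slot height,width image dimensions in pixels.
#' @slot nuclei data.frame with one row per nucleus: `center_row`,
#'   `center_col`, `radius` (pixels), `brightness` (expected photons per
#'   pixel over the full acquisition), `fret_fraction` (true FRETing
#'   population fraction in \[0,1\]) and `dox_uM` (true doxorubicin
#'   concentration).
#' @slot frame_rate_hz acquisition frame rate.
#' @slot n_frames number of frames in the acquisition window.
#' @slot period_ns excitation period (12.5 ns for an 80 MHz laser).
#' @slot n_bins number of TCSPC micro-time bins.
#' @slot background_rate expected background photons per pixel per frame.
#' @slot bleed_coeff acceptor bleed-through photon fraction per micromolar.
#' @slot edge_sigma Gaussian softness of the nucleus rim in pixels.
#' @slot seed integer seed recorded at construction.
#' @exportClass Scene
setClass("Scene", representation(
  height = "integer", width = "integer", nuclei = "data.frame",
  frame_rate_hz = "numeric", n_frames = "integer",
  period_ns = "numeric", n_bins = "integer",
  background_rate = "numeric", bleed_coeff = "numeric",
  edge_sigma = "numeric", seed = "integer"
))

setValidity("Scene", function(object) {
  msgs <- character()
  if (object@height < 1L || object@width < 1L)
    msgs <- c(msgs, "image dimensions must be positive (fields height/width)")
  if (object@n_bins < 2L) msgs <- c(msgs, "n_bins must be >= 2")
  if (object@period_ns <= 0) msgs <- c(msgs, "period_ns must be > 0")
  if (object@frame_rate_hz <= 0) msgs <- c(msgs, "frame_rate_hz must be > 0")
  if (object@n_frames < 1L) msgs <- c(msgs, "n_frames must be >= 1")
  if (object@background_rate < 0) msgs <- c(msgs, "background_rate must be >= 0")
  nuc <- object@nuclei
  if (nrow(nuc)) {
    need <- c("center_row", "center_col", "radius", "brightness",
              "fret_fraction", "dox_uM")
    if (!all(need %in% names(nuc)))
      msgs <- c(msgs, paste("nuclei must have columns:",
                            paste(need, collapse = ", ")))
    else {
      if (any(nuc$radius < 1)) msgs <- c(msgs, "nucleus radius must be >= 1")
      if (any(nuc$brightness <= 0)) msgs <- c(msgs, "nucleus brightness must be > 0")
      if (any(nuc$fret_fraction < 0 | nuc$fret_fraction > 1))
        msgs <- c(msgs, "fret_fraction must lie in [0, 1]")
      if (any(nuc$dox_uM < 0)) msgs <- c(msgs, "dox_uM must be >= 0")
      if (any(nuc$center_row < 1 | nuc$center_row > object@height |
              nuc$center_col < 1 | nuc$center_col > object@width))
        msgs <- c(msgs, "nucleus centers must lie within image bounds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Photon event stream
#'
#' FIFO-style TCSPC data: one row per detected photon carrying the frame
#' index, pixel position and micro-time bin, plus acquisition metadata.
#' Frame indices and pixel coordinates are 0-based; micro-time bins are
#' 0-based half-open in `[0, n_bins)`.
#'
#' @slot events data.frame with integer columns `frame`, `row`, `col`, `tbin`.
#' @slot height,width image dimensions in pixels.
#' @slot n_bins number of micro-time bins.
#' @slot period_ns excitation period in ns (`bin_width = period_ns / n_bins`).
#' @slot frame_rate_hz acquisition frame rate.
#' @exportClass PhotonEventStream
setClass("PhotonEventStream", representation(
  events = "data.frame", height = "integer", width = "integer",
  n_bins = "integer", period_ns = "numeric", frame_rate_hz = "numeric"
))

setValidity("PhotonEventStream", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("frame", "row", "col", "tbin")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (any(ev$frame < 0L)) msgs <- c(msgs, "field frame: must be >= 0")
    if (any(ev$row < 0L | ev$row >= object@height))
      msgs <- c(msgs, "field row: outside [0, height)")
    if (any(ev$col < 0L | ev$col >= object@width))
      msgs <- c(msgs, "field col: outside [0, width)")
    if (any(ev$tbin < 0L | ev$tbin >= object@n_bins))
      msgs <- c(msgs, "field tbin: outside [0, n_bins)")
  }
  if (object@period_ns <= 0) msgs <- c(msgs, "period_ns must be > 0")
  if (object@n_bins < 2L) msgs <- c(msgs, "n_bins must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' TCSPC decay histogram
#'
#' Photon counts per micro-time bin for one pixel, one nucleus or a pooled
#' region. After background correction counts may be non-integer and
#' negative; in that case per-bin variances are carried alongside so that
#' fitters can weight bins by counting statistics.
#'
#' @slot counts numeric vector of per-bin counts.
#' @slot period_ns excitation period in ns.
#' @slot origin_offset_ns temporal offset of bin 0 relative to the
#'   excitation pulse.
#' @slot variance per-bin variances (length 0 for raw Poisson counts).
#' @exportClass DecayHistogram
setClass("DecayHistogram", representation(
  counts = "numeric", period_ns = "numeric",
  origin_offset_ns = "numeric", variance = "numeric"
))

setValidity("DecayHistogram", function(object) {
  msgs <- character()
  if (length(object@counts) < 2L) msgs <- c(msgs, "need >= 2 bins")
  if (object@period_ns <= 0) msgs <- c(msgs, "period_ns must be > 0")
  if (length(object@variance) == 0L && any(object@counts < 0))
    msgs <- c(msgs, "raw counts must be >= 0 (negative values only allowed after background correction, with variances attached)")
  if (length(object@variance) &&
      length(object@variance) != length(object@counts))
    msgs <- c(msgs, "variance must match counts in length")
  if (length(msgs)) msgs else TRUE
})

#' Instrument response function profile
#'
#' Normalized IRF density over the micro-time bins (sums to 1) plus a
#' temporal offset calibrated from a reference dye of known lifetime.
#'
#' @slot density normalized per-bin IRF weights.
#' @slot temporal_offset_ns offset applied before convolution.
#' @exportClass IRFProfile
setClass("IRFProfile", representation(
  density = "numeric", temporal_offset_ns = "numeric"
))

setValidity("IRFProfile", function(object) {
  msgs <- character()
  if (any(object@density < 0)) msgs <- c(msgs, "IRF density must be non-negative")
  if (abs(sum(object@density) - 1) > 1e-9)
    msgs <- c(msgs, "IRF density must sum to 1 (within 1e-9)")
  if (length(msgs)) msgs else TRUE
})

#' Frame alignment report
#'
#' Per-frame result of normalized cross-correlation registration against
#' the reference template: integer shift, NCC score at the peak, and the
#' accept/reject gating decision.
#'
#' @slot frames data.frame with columns `frame` (0-based), `d_row`,
#'   `d_col`, `score`, `accepted`.
#' @slot template_region integer `(row0, col0, height, width)` of the
#'   template within the reference frame (1-based origin).
#' @slot threshold NCC acceptance threshold used.
#' @slot search_range maximum absolute shift searched, pixels.
#' @slot reference_frame 0-based index of the reference frame.
#' @exportClass AlignmentReport
setClass("AlignmentReport", representation(
  frames = "data.frame", template_region = "integer",
  threshold = "numeric", search_range = "integer",
  reference_frame = "integer"
))

setValidity("AlignmentReport", function(object) {
  fr <- object@frames
  need <- c("frame", "d_row", "d_col", "score", "accepted")
  if (!all(need %in% names(fr)))
    return(paste("frames must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  ok <- !is.na(fr$score)
  if (any(fr$accepted[ok] & fr$score[ok] < object@threshold))
    msgs <- c(msgs, "accepted frames must have score >= threshold")
  s <- object@search_range
  if (any(abs(fr$d_row[fr$accepted]) > s | abs(fr$d_col[fr$accepted]) > s))
    msgs <- c(msgs, "shifts exceed the search range")
  if (length(msgs)) msgs else TRUE
})

#' Pooled FLIM image
#'
#' Motion-gated accumulation of photon events onto the reference grid: a
#' `height x width x n_bins` array of per-pixel decay counts, with the
#' number of contributing frames and the count of events dropped because
#' alignment mapped them off the grid.
#'
#' @slot counts integer array `[height, width, n_bins]`.
#' @slot n_frames_used frames that passed the gate.
#' @slot n_dropped_oob events dropped as out of bounds after shifting.
#' @slot period_ns excitation period in ns.
#' @slot frame_rate_hz acquisition frame rate.
#' @exportClass PooledFLIMImage
setClass("PooledFLIMImage", representation(
  counts = "array", n_frames_used = "integer", n_dropped_oob = "integer",
  period_ns = "numeric", frame_rate_hz = "numeric"
))

setValidity("PooledFLIMImage", function(object) {
  msgs <- character()
  if (length(dim(object@counts)) != 3L)
    msgs <- c(msgs, "counts must be a 3-d array [height, width, n_bins]")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (object@n_frames_used < 0L) msgs <- c(msgs, "n_frames_used must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Calibration table
#'
#' Dose-response calibration linking doxorubicin concentration to the
#' non-FRETing donor population fraction measured in vitro, together with
#' the fixed bi-exponential lifetime components and the linear acceptor
#' bleed-through coefficient. Rows are sorted by strictly increasing
#' concentration starting at 0.
#'
#' @slot table data.frame with columns `concentration_uM`,
#'   `nonfret_fraction`.
#' @slot bleed_coeff photon fraction per micromolar.
#' @slot tau_long_ps,tau_short_ps fixed donor lifetime components.
#' @exportClass CalibrationTable
setClass("CalibrationTable", representation(
  table = "data.frame", bleed_coeff = "numeric",
  tau_long_ps = "numeric", tau_short_ps = "numeric"
))

setValidity("CalibrationTable", function(object) {
  tab <- object@table
  msgs <- character()
  if (!all(c("concentration_uM", "nonfret_fraction") %in% names(tab)))
    return("table must have columns concentration_uM, nonfret_fraction")
  cc <- tab$concentration_uM
  if (length(cc) < 2L) msgs <- c(msgs, "need >= 2 calibration points")
  if (any(diff(cc) <= 0))
    msgs <- c(msgs, "concentrations must be strictly increasing (no duplicates)")
  if (length(cc) && cc[1] != 0) msgs <- c(msgs, "first concentration must be 0")
  fr <- tab$nonfret_fraction
  if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "nonfret_fraction must lie in [0, 1]")
  if (length(fr) && fr[1] < max(fr))
    msgs <- c(msgs, "nonfret_fraction at C = 0 must be the column maximum")
  if (object@tau_short_ps >= object@tau_long_ps)
    msgs <- c(msgs, "tau_short_ps must be < tau_long_ps")
  if (length(msgs)) msgs else TRUE
})

#' Single-exponential pixel fit
#'
#' @slot tau_ps fitted lifetime in picoseconds.
#' @slot amplitude fitted total signal photons.
#' @slot background_level fitted background photons per bin.
#' @slot fit_quality reduced Pearson chi-square.
#' @slot n_photons photons in the fitted histogram.
#' @slot converged FALSE when the optimum sits on the search boundary.
#' @exportClass SingleExpFit
setClass("SingleExpFit", representation(
  tau_ps = "numeric", amplitude = "numeric", background_level = "numeric",
  fit_quality = "numeric", n_photons = "numeric", converged = "logical"
))

#' Global bi-exponential fit
#'
#' Result of globally fitting a set of decay histograms (typically one per
#' nucleus) to a two-component donor model with a fixed long lifetime and
#' a shared short lifetime, each histogram keeping its own FRETing
#' population fraction `f`.
#'
#' @slot tau_long_ps fixed non-FRETing donor lifetime.
#' @slot tau_short_ps shared FRETing lifetime (fixed or globally fitted).
#' @slot tau_short_fitted TRUE when tau_short was free in the fit.
#' @slot fractions per-histogram FRETing population fraction f in \[0,1\].
#' @slot bg_fractions per-histogram uniform-background photon fraction.
#' @slot tau_mean_iw_ps per-histogram intensity-weighted mean lifetime.
#' @slot n_photons per-histogram photon totals.
#' @slot converged per-histogram convergence flags.
#' @slot logLik joint Poisson log-likelihood at the optimum.
#' @exportClass BiExpGlobalFit
setClass("BiExpGlobalFit", representation(
  tau_long_ps = "numeric", tau_short_ps = "numeric",
  tau_short_fitted = "logical", fractions = "numeric",
  bg_fractions = "numeric", tau_mean_iw_ps = "numeric",
  n_photons = "numeric", converged = "logical", logLik = "numeric"
))

setValidity("BiExpGlobalFit", function(object) {
  msgs <- character()
  if (any(object@fractions < -1e-9 | object@fractions > 1 + 1e-9))
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (object@tau_short_ps >= object@tau_long_ps)
    msgs <- c(msgs, "tau_short_ps must be < tau_long_ps")
  tm <- object@tau_mean_iw_ps
  if (any(tm < object@tau_short_ps - 1e-6 | tm > object@tau_long_ps + 1e-6))
    msgs <- c(msgs, "tau_mean_iw must lie within [tau_short, tau_long]")
  if (length(msgs)) msgs else TRUE
})
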