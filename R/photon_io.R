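#' @include AllClasses.R
NULL

# Event streams are stored as an open columnar text format: '#key=value'
# metadata header lines followed by a CSV body with integer columns
# frame,row,col,tbin (all 0-based). Events are written in (frame,row,col,
# tbin) sort order so that write/read round-trips are bit-exact.

parseHeader <- function(lines) {
  kv <- sub("^#", "", lines)
  parts <- strsplit(kv, "=", fixed = TRUE)
  vals <- vapply(parts, function(p) paste(p[-1], collapse = "="), character(1))
  names(vals) <- vapply(parts, `[[`, character(1), 1)
  vals
}

headerNum <- function(hdr, key, path) {
  if (!key %in% names(hdr))
    stop("malformed event file ", path, ": missing header field '", key, "'",
         call. = FALSE)
  v <- suppressWarnings(as.numeric(hdr[[key]]))
  if (is.na(v))
    stop("malformed event file ", path, ": field '", key,
         "' is not numeric", call. = FALSE)
  v
}

#' Write / read a photon event stream
#'
#' `writeEventStream()` stores a [PhotonEventStream-class] to a plain-text
#' file (metadata header plus CSV event columns); `readEventStream()`
#' parses and validates it. On valid input the pair is a bit-exact
#' round-trip.
#'
#' @param stream a [PhotonEventStream-class].
#' @param path file path.
#' @return `readEventStream` returns a [PhotonEventStream-class];
#'   `writeEventStream` returns `path` invisibly.
#' @export
writeEventStream <- function(stream, path) {
  stopifnot(is(stream, "PhotonEventStream"))
  validObject(stream)
  ev <- stream@events
  ev <- ev[order(ev$frame, ev$row, ev$col, ev$tbin), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#height=%d", stream@height),
    sprintf("#width=%d", stream@width),
    sprintf("#n_time_bins=%d", stream@n_bins),
    sprintf("#bin_width_ns=%.17g", stream@period_ns / stream@n_bins),
    sprintf("#period_ns=%.17g", stream@period_ns),
    sprintf("#frame_rate_hz=%.17g", stream@frame_rate_hz)
  ), con)
  write.csv(ev, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventStream
#' @export
readEventStream <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  n_hdr <- which(!is_hdr)[1] - 1L
  hdr <- parseHeader(lines[seq_len(n_hdr)])
  ev <- read.csv(text = lines[-seq_len(n_hdr)],
                 colClasses = c("integer", "integer", "integer", "integer"))
  need <- c("frame", "row", "col", "tbin")
  if (!identical(names(ev), need))
    stop("malformed event file ", path, ": expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  new("PhotonEventStream", events = ev,
      height = as.integer(headerNum(hdr, "height", path)),
      width = as.integer(headerNum(hdr, "width", path)),
      n_bins = as.integer(headerNum(hdr, "n_time_bins", path)),
      period_ns = headerNum(hdr, "period_ns", path),
      frame_rate_hz = headerNum(hdr, "frame_rate_hz", path))
}

#' Construct a photon event stream
#'
#' @param events data.frame with integer 0-based columns `frame`, `row`,
#'   `col`, `tbin`.
#' @param height,width image dimensions, pixels.
#' @param n_bins number of micro-time bins.
#' @param period_ns excitation period, ns.
#' @param frame_rate_hz acquisition frame rate.
#' @return a validated [PhotonEventStream-class].
#' @export
photonEventStream <- function(events, height, width, n_bins,
                              period_ns = 12.5, frame_rate_hz = 8.5) {
  events <- as.data.frame(events)
  for (cn in c("frame", "row", "col", "tbin"))
    events[[cn]] <- as.integer(events[[cn]])
  new("PhotonEventStream", events = events, height = as.integer(height),
      width = as.integer(width), n_bins = as.integer(n_bins),
      period_ns = period_ns, frame_rate_hz = frame_rate_hz)
}

#' Read a calibration table
#'
#' Parses a CSV dose-response calibration with columns
#' `concentration_uM`, `nonfret_fraction` and optional `#key=value`
#' header lines for `bleed_coeff`, `tau_long_ps`, `tau_short_ps` (which
#' the corresponding arguments override). Rows are sorted by
#' concentration; duplicate concentrations, fractions outside \[0,1\] or
#' a non-maximal fraction at C = 0 are rejected.
#'
#' @param path CSV file path.
#' @param bleed_coeff,tau_long_ps,tau_short_ps overrides for the header
#'   values (defaults 0.01 / 2460 / 770 when neither is present).
#' @return a [CalibrationTable-class].
#' @export
readCalibrationTable <- function(path, bleed_coeff = NULL,
                                 tau_long_ps = NULL, tau_short_ps = NULL) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- parseHeader(lines[is_hdr])
  tab <- read.csv(text = lines[!is_hdr])
  stopIfNot(all(c("concentration_uM", "nonfret_fraction") %in% names(tab)),
            "calibration CSV must have columns concentration_uM, nonfret_fraction")
  tab <- tab[order(tab$concentration_uM),
             c("concentration_uM", "nonfret_fraction")]
  rownames(tab) <- NULL
  if (anyDuplicated(tab$concentration_uM))
    stop("calibration table has duplicate concentrations", call. = FALSE)
  pick <- function(arg, key, default) {
    if (!is.null(arg)) arg
    else if (key %in% names(hdr)) as.numeric(hdr[[key]])
    else default
  }
  new("CalibrationTable", table = tab,
      bleed_coeff = pick(bleed_coeff, "bleed_coeff", 0.01),
      tau_long_ps = pick(tau_long_ps, "tau_long_ps", 2460),
      tau_short_ps = pick(tau_short_ps, "tau_short_ps", 770))
}

#' Packaged synthetic calibration table
#'
#' The default dose-response table shipped with the package: a synthetic
#' logistic-saturation curve (`f(C) = 0.7 C / (C + 1 uM)`) evaluated at
#' the standard dose ladder 0, 0.18, 0.9, 1.8, 9, 18 uM, with CEM
#' lifetime components 2460/770 ps and a 1 %/uM bleed-through
#' coefficient. It is a stand-in with the qualitative shape of measured
#' calibrations (steepest at sub-micromolar doses, plateauing at high
#' doses), not measured data.
#'
#' @return a [CalibrationTable-class].
#' @export
defaultCalibration <- function() {
  readCalibrationTable(system.file("extdata", "calibration_synthetic.csv",
                                   package = "flimfret", mustWork = TRUE))
}

#' Write an intensity stack as multi-page 16-bit TIFF
#'
#' @param images a list of equal-shaped numeric matrices, a single
#'   matrix, or a `height x width x n` array.
#' @param path output file path.
#' @return `path`, invisibly. Values above 65535 are clipped with a
#'   warning.
#' @export
writeIntensityStack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  stopIfNot(is.list(images) && length(images) > 0,
            "images must be a non-empty stack")
  d <- dim(images[[1]])
  stopIfNot(all(vapply(images, function(m) identical(dim(m), d), logical(1))),
            "all images in the stack must share one shape")
  if (any(vapply(images, function(m) any(m > 65535), logical(1)))) {
    warning("intensity values above 65535 clipped to the 16-bit maximum")
    images <- lapply(images, function(m) pmin(m, 65535))
  }
  stopIfNot(all(vapply(images, function(m) all(m >= 0), logical(1))),
            "intensity values must be >= 0")
  tiff::writeTIFF(lapply(images, function(m) round(m) / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read an intensity stack written by [writeIntensityStack()]
#'
#' @param path TIFF file path.
#' @return list of numeric count matrices.
#' @export
readIntensityStack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) round(m * 65535))
}

#' Write a label map as 16-bit TIFF
#'
#' @param labels integer label matrix (0 = background).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(labels, path) {
  writeIntensityStack(list(labels), path)
}
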