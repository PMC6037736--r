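#' @include AllClasses.R AllGenerics.R
NULL

#' Frames in an accumulation window
#'
#' Number of whole frames in a time window: `floor(duration * rate)`.
#' At the instrument's 8.5 Hz a 10 s window holds 85 frames.
#'
#' @param duration_s window duration, seconds (> 0).
#' @param frame_rate_hz frame rate, Hz (> 0).
#' @return integer frame count.
#' @examples
#' framesInWindow(10, 8.5)  # 85
#' @export
framesInWindow <- function(duration_s, frame_rate_hz) {
  stopIfNot(duration_s > 0, "duration_s must be > 0")
  stopIfNot(frame_rate_hz > 0, "frame_rate_hz must be > 0")
  as.integer(floor(duration_s * frame_rate_hz))
}

#' Register one frame against a reference template
#'
#' Exhaustive normalized cross-correlation over integer shifts: for every
#' candidate shift within `+/- search_range` pixels the Pearson
#' correlation between the template and the correspondingly displaced
#' frame patch is evaluated, and the peak is returned. The returned shift
#' is the displacement of the frame content relative to the reference
#' grid (the template is found at its reference position plus the shift).
#' Ties are broken by smallest Euclidean shift magnitude, then row-major
#' order, so registration is deterministic.
#'
#' @param frame_image numeric matrix (one frame's intensity image).
#' @param template numeric sub-image cut from the reference frame; must
#'   be strictly smaller than the frame and have nonzero variance.
#' @param template_origin `(row, col)` 1-based position of the template's
#'   top-left corner within the reference grid.
#' @param search_range maximum absolute shift searched, pixels.
#' @return list with `shift` (integer `c(d_row, d_col)`) and `score`
#'   (NCC value at the peak, in \[-1, 1\]).
#' @export
registerFrame <- function(frame_image, template, template_origin,
                          search_range = 15L) {
  th <- nrow(template); tw <- ncol(template)
  stopIfNot(th < nrow(frame_image) || tw < ncol(frame_image),
            "template must be smaller than the frame")
  tv <- as.vector(template)
  tsd <- sd(tv)
  if (!is.finite(tsd) || tsd == 0)
    stop("template has zero variance: NCC is undefined", call. = FALSE)
  tc <- tv - mean(tv)
  tnorm <- sqrt(sum(tc^2))
  r0 <- template_origin[1]; c0 <- template_origin[2]
  s <- as.integer(search_range)
  best_score <- -Inf; best <- c(0L, 0L); best_mag <- Inf
  for (dr in -s:s) {
    rr <- r0 + dr
    if (rr < 1 || rr + th - 1 > nrow(frame_image)) next
    for (dc in -s:s) {
      cc <- c0 + dc
      if (cc < 1 || cc + tw - 1 > ncol(frame_image)) next
      patch <- frame_image[rr:(rr + th - 1), cc:(cc + tw - 1)]
      pv <- as.vector(patch)
      pc <- pv - mean(pv)
      pnorm <- sqrt(sum(pc^2))
      score <- if (pnorm == 0) 0 else sum(tc * pc) / (tnorm * pnorm)
      mag <- dr * dr + dc * dc
      if (score > best_score + 1e-12 ||
          (abs(score - best_score) <= 1e-12 && mag < best_mag)) {
        best_score <- score; best <- c(dr, dc); best_mag <- mag
      }
    }
  }
  list(shift = as.integer(best), score = best_score)
}

gaussianSmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

#' Align all frames of an event stream
#'
#' Builds per-frame intensity images (optionally Gaussian-smoothed, since
#' single 8.5 Hz frames are photon-sparse), registers each against a
#' template from the reference frame with [registerFrame()], and gates
#' frames by their NCC score: frames scoring at least `threshold`
#' (default 0.9; 0.8 is used for low signal-to-noise acquisitions) are
#' accepted, the rest are rejected as motion-distorted.
#'
#' @param stream a [PhotonEventStream-class].
#' @param threshold NCC acceptance threshold.
#' @param search_range maximum absolute shift searched, pixels.
#' @param template optional numeric matrix; default is the central
#'   50 %-area sub-region of the reference frame.
#' @param template_origin `(row, col)` 1-based top-left of `template`;
#'   required when `template` is supplied.
#' @param reference_frame 0-based index of the reference frame, or
#'   `NULL` (default) to select it automatically: frames are
#'   pre-screened against a template cut from the pixel-wise median
#'   image, and the first frame scoring at least `threshold` (falling
#'   back to the best-scoring frame) becomes the reference. This keeps a
#'   breathing-distorted first frame from poisoning the template.
#' @param smooth_sigma Gaussian smoothing (pixels) applied to frame
#'   images before NCC; 0 disables.
#' @return an [AlignmentReport-class].
#' @export
alignFrames <- function(stream, threshold = 0.9, search_range = 15L,
                        template = NULL, template_origin = NULL,
                        reference_frame = NULL, smooth_sigma = 1) {
  ev <- stream@events
  stopIfNot(nrow(ev) > 0, "event stream is empty")
  nf <- max(ev$frame) + 1L
  H <- stream@height; W <- stream@width
  imgs <- lapply(0:(nf - 1L), function(f)
    gaussianSmooth(intensityImage(stream, frame = f), smooth_sigma))
  # central sub-region covering 50% of the frame area
  th <- round(H / sqrt(2)); tw <- round(W / sqrt(2))
  r0 <- floor((H - th) / 2) + 1L; c0 <- floor((W - tw) / 2) + 1L
  if (is.null(reference_frame)) {
    if (nf == 1L) reference_frame <- 0L
    else {
      med <- apply(simplify2array(imgs), c(1, 2), median)
      med_tpl <- med[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)]
      best_i <- 0L; best_s <- -Inf
      for (f in seq_len(nf)) {
        s <- registerFrame(imgs[[f]], med_tpl, c(r0, c0),
                           search_range)$score
        if (s >= threshold) { best_i <- f - 1L; break }
        if (s > best_s) { best_s <- s; best_i <- f - 1L }
      }
      reference_frame <- best_i
    }
  }
  ref <- imgs[[reference_frame + 1L]]
  if (is.null(template)) {
    template <- ref[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)]
    template_origin <- c(r0, c0)
  } else {
    stopIfNot(!is.null(template_origin),
              "template_origin is required with a user template")
  }
  res <- lapply(imgs, registerFrame, template = template,
                template_origin = template_origin,
                search_range = search_range)
  d_row <- vapply(res, function(x) x$shift[1], integer(1))
  d_col <- vapply(res, function(x) x$shift[2], integer(1))
  score <- vapply(res, `[[`, numeric(1), "score")
  new("AlignmentReport",
      frames = data.frame(frame = 0:(nf - 1L), d_row = d_row,
                          d_col = d_col, score = score,
                          accepted = score >= threshold),
      template_region = as.integer(c(template_origin, dim(template))),
      threshold = threshold, search_range = as.integer(search_range),
      reference_frame = as.integer(reference_frame))
}

#' Gate and accumulate photon events onto the reference grid
#'
#' Events of accepted frames are translated by minus their frame's
#' measured shift, mapping them back onto the reference grid, and
#' accumulated into a per-pixel decay-count array. Events that land
#' outside the grid are dropped and counted; rejected frames contribute
#' nothing.
#'
#' @param stream a [PhotonEventStream-class].
#' @param report an [AlignmentReport-class] covering all frames of the
#'   stream.
#' @return a [PooledFLIMImage-class]. An all-rejected report yields an
#'   empty pooled image with a warning.
#' @export
gateAndAccumulate <- function(stream, report) {
  ev <- stream@events
  fr <- report@frames
  if (nrow(ev) && max(ev$frame) > max(fr$frame))
    stop("alignment report does not cover all frames in the stream",
         call. = FALSE)
  H <- stream@height; W <- stream@width; B <- stream@n_bins
  acc <- fr$frame[fr$accepted]
  counts <- array(0L, dim = c(H, W, B))
  dropped <- 0L
  if (length(acc) == 0L) {
    warning("all frames rejected: pooled image is empty")
  } else {
    keep <- ev$frame %in% acc
    e <- ev[keep, , drop = FALSE]
    shift_row <- setNames(fr$d_row, fr$frame)
    shift_col <- setNames(fr$d_col, fr$frame)
    r <- e$row - shift_row[as.character(e$frame)]
    cl <- e$col - shift_col[as.character(e$frame)]
    inb <- r >= 0L & r < H & cl >= 0L & cl < W
    dropped <- sum(!inb)
    if (dropped > 0)
      message(dropped, " events mapped outside the reference grid were dropped")
    idx <- 1L + r[inb] + cl[inb] * H + e$tbin[inb] * (H * W)
    tab <- tabulate(idx, nbins = H * W * B)
    counts[] <- as.integer(tab)
  }
  new("PooledFLIMImage", counts = counts,
      n_frames_used = length(acc), n_dropped_oob = as.integer(dropped),
      period_ns = stream@period_ns, frame_rate_hz = stream@frame_rate_hz)
}
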