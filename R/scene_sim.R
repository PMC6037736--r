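#' @include AllClasses.R decay_fit.R
NULL

#' Donor/acceptor decay model parameters for simulation
#'
#' Bundles the lifetimes used when sampling photon micro-times: the
#' non-FRETing and FRETing donor components and the lifetime assigned to
#' doxorubicin bleed-through photons. The doxorubicin lifetime is a
#' configurable assumption, not a calibrated constant.
#'
#' @param tau_long_ps non-FRETing donor lifetime, ps.
#' @param tau_short_ps FRETing donor lifetime, ps.
#' @param dox_tau_ps lifetime of acceptor bleed-through photons, ps.
#' @param irf optional [IRFProfile-class] convolved into every component.
#' @return list of simulation decay parameters.
#' @export
decayModel <- function(tau_long_ps = 2460, tau_short_ps = 770,
                       dox_tau_ps = 1000, irf = NULL) {
  stopIfNot(tau_short_ps > 0 && tau_long_ps > tau_short_ps,
            "need 0 < tau_short_ps < tau_long_ps")
  stopIfNot(dox_tau_ps > 0, "dox_tau_ps must be > 0")
  list(tau_long_ps = tau_long_ps, tau_short_ps = tau_short_ps,
       dox_tau_ps = dox_tau_ps, irf = irf)
}

placeNuclei <- function(n, height, width, radius_range, brightness_range,
                        fret_range, min_gap = 3) {
  rows <- numeric(0); cols <- numeric(0); rad <- numeric(0)
  tries <- 0L
  while (length(rows) < n) {
    tries <- tries + 1L
    if (tries > 5000L)
      stop("could not place ", n, " non-overlapping nuclei in a ",
           height, " x ", width, " image", call. = FALSE)
    r <- runif(1, radius_range[1], radius_range[2])
    m <- ceiling(r) + 2
    if (height - 2 * m < 1 || width - 2 * m < 1)
      stop("image too small for nuclei of radius ", radius_range[2],
           call. = FALSE)
    cr <- runif(1, m + 1, height - m)
    cc <- runif(1, m + 1, width - m)
    if (length(rows)) {
      d <- sqrt((rows - cr)^2 + (cols - cc)^2)
      if (any(d < rad + r + min_gap)) next
    }
    rows <- c(rows, cr); cols <- c(cols, cc); rad <- c(rad, r)
  }
  data.frame(center_row = rows, center_col = cols, radius = rad,
             brightness = runif(n, brightness_range[1], brightness_range[2]),
             fret_fraction = runif(n, fret_range[1], fret_range[2]))
}

#' Create a synthetic acquisition scene
#'
#' Builds a ground-truth scene with the statistical structure of the
#' endomicroscope acquisitions: 118 x 172 pixel frames at 8.5 Hz, 256
#' micro-time bins over a 12.5 ns excitation period (80 MHz), and nuclei
#' bright enough to collect 400-1000 photons per pixel over the 10 s
#' (85-frame) window. Nuclei are hard-edged discs with a Gaussian rim of
#' width `edge_sigma`. Each nucleus carries a true FRETing population
#' fraction; its true doxorubicin concentration is derived from that
#' fraction through `calib` so that simulation truth and calibration
#' inversion are mutually consistent.
#'
#' @param height,width image dimensions, pixels.
#' @param n_nuclei number of nuclei to place (ignored when `nuclei` is
#'   given).
#' @param nuclei optional data.frame overriding random placement; columns
#'   `center_row`, `center_col`, `radius`, `brightness`, `fret_fraction`
#'   and optionally `dox_uM`.
#' @param radius_range,brightness_range,fret_range sampling ranges for
#'   random nuclei (brightness = expected photons per pixel over the full
#'   acquisition window).
#' @param frame_rate_hz,n_frames,period_ns,n_bins acquisition constants.
#' @param background_rate expected background photons per pixel per frame.
#' @param bleed_coeff acceptor bleed-through photon fraction per uM.
#' @param calib [CalibrationTable-class] used to derive `dox_uM` from
#'   `fret_fraction`; default [defaultCalibration()]. Fractions outside
#'   the calibrated range map to censored bounds.
#' @param edge_sigma Gaussian softness of the nucleus rim, pixels.
#' @param seed integer seed; identical parameters and seed give an
#'   identical scene.
#' @return a [Scene-class].
#' @export
makeScene <- function(height = 118L, width = 172L, n_nuclei = 12L,
                      nuclei = NULL,
                      radius_range = c(5, 10),
                      brightness_range = c(400, 1000),
                      fret_range = c(0.1, 0.6),
                      frame_rate_hz = 8.5, n_frames = 85L,
                      period_ns = 12.5, n_bins = 256L,
                      background_rate = 0.1, bleed_coeff = 0.01,
                      calib = NULL, edge_sigma = 1, seed = 1L) {
  stopIfNot(height >= 1 && width >= 1,
            "image dimensions must be positive (fields height/width)")
  if (is.null(nuclei)) {
    nuclei <- withSeed(substreamSeed(seed, "nuclei"),
                       placeNuclei(n_nuclei, height, width, radius_range,
                                   brightness_range, fret_range))
  }
  if (is.null(nuclei$dox_uM) && nrow(nuclei)) {
    if (is.null(calib)) calib <- defaultCalibration()
    lut <- buildConcentrationLut(calib)
    nuclei$dox_uM <- vapply(nuclei$fret_fraction, function(f)
      estimateConcentration(f, lut)$value, numeric(1))
  } else if (is.null(nuclei$dox_uM)) {
    nuclei$dox_uM <- numeric(0)
  }
  new("Scene", height = as.integer(height), width = as.integer(width),
      nuclei = nuclei, frame_rate_hz = frame_rate_hz,
      n_frames = as.integer(n_frames), period_ns = period_ns,
      n_bins = as.integer(n_bins), background_rate = background_rate,
      bleed_coeff = bleed_coeff, edge_sigma = edge_sigma,
      seed = as.integer(seed))
}

# Expected signal photons per pixel over the full acquisition window
# (nuclei only, no background), on the reference grid.
expectedSignalImage <- function(scene) {
  img <- matrix(0, scene@height, scene@width)
  nuc <- scene@nuclei
  for (i in seq_len(nrow(nuc))) {
    img <- img + nucleusProfile(scene, i)
  }
  img
}

nucleusProfile <- function(scene, i) {
  nuc <- scene@nuclei[i, ]
  img <- matrix(0, scene@height, scene@width)
  ext <- ceiling(nuc$radius + 3 * scene@edge_sigma + 1)
  r0 <- max(1, floor(nuc$center_row - ext))
  r1 <- min(scene@height, ceiling(nuc$center_row + ext))
  c0 <- max(1, floor(nuc$center_col - ext))
  c1 <- min(scene@width, ceiling(nuc$center_col + ext))
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - nuc$center_row)^2, (cols - nuc$center_col)^2, "+"))
  prof <- ifelse(d <= nuc$radius, 1,
                 if (scene@edge_sigma > 0)
                   exp(-(d - nuc$radius)^2 / (2 * scene@edge_sigma^2))
                 else 0)
  img[rows, cols] <- nuc$brightness * prof
  img
}

#' Simulate breathing-like frame motion
#'
#' Frame-to-frame translation follows a bounded integer random walk
#' (amplitude = the reflecting bound, pixels), emulating slow tissue
#' drift; a random fraction `distortion_prob` of frames is additionally
#' flagged as distorted, emulating the large non-rigid deformations
#' during breathing that make a frame unalignable.
#'
#' @param scene a [Scene-class].
#' @param amplitude reflecting bound of the random walk, pixels (>= 0).
#' @param distortion_prob per-frame probability of a distortion event.
#' @param warp_scale magnitude of the non-rigid warp (pixels): distorted
#'   frames receive a random affine deformation whose translation and
#'   edge-of-field differential displacement each have magnitude drawn
#'   uniformly from `[warp_scale, 2 * warp_scale]` with random sign
#'   (so a flagged frame is always substantially deformed), plus 1 px of
#'   local scatter, applied by [samplePhotonEvents()].
#' @param seed integer seed.
#' @return data.frame with one row per frame: `frame` (0-based), `d_row`,
#'   `d_col` (integer shift of the frame content relative to the
#'   reference grid), `distorted`, and the warp parameters
#'   `warp_t_row`, `warp_t_col`, `warp_g_rr`, `warp_g_rc`, `warp_g_cr`,
#'   `warp_g_cc` (all zero for clean frames).
#' @export
simulateMotion <- function(scene, amplitude = 3, distortion_prob = 0.2,
                           warp_scale = 4, seed = 1L) {
  stopIfNot(amplitude >= 0, "amplitude must be >= 0")
  stopIfNot(distortion_prob >= 0 && distortion_prob <= 1,
            "distortion_prob must lie in [0, 1]")
  nf <- scene@n_frames
  withSeed(substreamSeed(seed, "motion"), {
    d_row <- integer(nf); d_col <- integer(nf)
    if (amplitude > 0) {
      pr <- pc <- 0L
      for (i in seq_len(nf)) {
        pr <- pr + sample(c(-1L, 0L, 1L), 1)
        pc <- pc + sample(c(-1L, 0L, 1L), 1)
        pr <- max(-amplitude, min(amplitude, pr))
        pc <- max(-amplitude, min(amplitude, pc))
        d_row[i] <- pr; d_col[i] <- pc
      }
    }
    distorted <- runif(nf) < distortion_prob
    half_r <- scene@height / 2; half_c <- scene@width / 2
    draw <- function() ifelse(distorted,
                              sample(c(-1, 1), nf, replace = TRUE) *
                                runif(nf, warp_scale, 2 * warp_scale), 0)
    data.frame(frame = 0:(nf - 1L), d_row = d_row, d_col = d_col,
               distorted = distorted,
               warp_t_row = draw(), warp_t_col = draw(),
               warp_g_rr = draw() / half_r, warp_g_rc = draw() / half_c,
               warp_g_cr = draw() / half_r, warp_g_cc = draw() / half_c)
  })
}

#' Sample a photon event stream from a scene
#'
#' Emulates FIFO-mode TCSPC acquisition. Per pixel and frame, photon
#' counts are Poisson with mean `nucleus brightness / n_frames +
#' background_rate`; micro-time bins are drawn from each nucleus' mixture
#' decay (non-FRETing donor, FRETing donor, and a doxorubicin
#' bleed-through component whose photon fraction is
#' `bleed_coeff * dox_uM`), while background photons are uniform over the
#' excitation period. Nucleus photons are displaced by the frame's motion
#' shift; photons in distorted frames are additionally deformed by the
#' frame's random affine warp plus 1 px of local scatter, emulating
#' non-rigid breathing deformation. Events displaced off the image are
#' dropped.
#'
#' @param scene a [Scene-class].
#' @param trajectory per-frame motion from [simulateMotion()] (or `NULL`
#'   for a static acquisition).
#' @param decay simulation decay parameters from [decayModel()].
#' @param seed integer seed; identical inputs give an identical stream.
#' @return a [PhotonEventStream-class] with events sorted by
#'   (frame, row, col, tbin).
#' @export
samplePhotonEvents <- function(scene, trajectory = NULL,
                               decay = decayModel(), seed = 1L) {
  nf <- scene@n_frames
  if (is.null(trajectory))
    trajectory <- data.frame(frame = 0:(nf - 1L), d_row = 0L, d_col = 0L,
                             distorted = FALSE, warp_t_row = 0,
                             warp_t_col = 0, warp_g_rr = 0, warp_g_rc = 0,
                             warp_g_cr = 0, warp_g_cc = 0)
  stopIfNot(nrow(trajectory) == nf,
            "trajectory length does not match scene n_frames")
  H <- scene@height; W <- scene@width; B <- scene@n_bins
  frames_l <- list(); rows_l <- list(); cols_l <- list(); tbins_l <- list()
  withSeed(substreamSeed(seed, "photons"), {
    # uniform instrument background: independent of tissue motion
    lam_bg <- scene@background_rate * H * W * nf
    if (lam_bg > 0) {
      nbg <- rpois(1, lam_bg)
      if (nbg > 0) {
        frames_l[[1]] <- sample.int(nf, nbg, replace = TRUE) - 1L
        rows_l[[1]] <- sample.int(H, nbg, replace = TRUE) - 1L
        cols_l[[1]] <- sample.int(W, nbg, replace = TRUE) - 1L
        tbins_l[[1]] <- sample.int(B, nbg, replace = TRUE) - 1L
      }
    }
    nuc <- scene@nuclei
    for (i in seq_len(nrow(nuc))) {
      prof <- nucleusProfile(scene, i)
      lam_tot <- sum(prof)
      if (lam_tot <= 0) next
      ntot <- rpois(1, lam_tot)
      if (ntot == 0) next
      pix <- sample.int(H * W, ntot, replace = TRUE, prob = as.vector(prof))
      fr <- sample.int(nf, ntot, replace = TRUE) - 1L
      r <- (pix - 1L) %% H
      cl <- (pix - 1L) %/% H
      # displace by the frame's rigid shift, plus the frame's affine
      # warp (and local scatter) when distorted
      ti <- fr + 1L
      r <- r + trajectory$d_row[ti]
      cl <- cl + trajectory$d_col[ti]
      warped <- trajectory$distorted[ti]
      if (any(warped)) {
        dr0 <- r[warped] - (H - 1) / 2
        dc0 <- cl[warped] - (W - 1) / 2
        nw <- sum(warped)
        r[warped] <- r[warped] + round(
          trajectory$warp_t_row[ti][warped] +
            trajectory$warp_g_rr[ti][warped] * dr0 +
            trajectory$warp_g_rc[ti][warped] * dc0 + rnorm(nw, 0, 1))
        cl[warped] <- cl[warped] + round(
          trajectory$warp_t_col[ti][warped] +
            trajectory$warp_g_cr[ti][warped] * dr0 +
            trajectory$warp_g_cc[ti][warped] * dc0 + rnorm(nw, 0, 1))
      }
      bt <- min(scene@bleed_coeff * nuc$dox_uM[i], 0.5)
      ws <- (1 - bt) * popToPhotonWeight(nuc$fret_fraction[i],
                                         decay$tau_short_ps,
                                         decay$tau_long_ps)
      wl <- (1 - bt) - ws
      curve <- expectedDecay(list(c(wl, decay$tau_long_ps),
                                  c(ws, decay$tau_short_ps),
                                  c(bt, decay$dox_tau_ps)),
                             decay$irf, scene@period_ns, B)
      tb <- sample.int(B, ntot, replace = TRUE, prob = curve) - 1L
      keep <- r >= 0L & r < H & cl >= 0L & cl < W
      k <- length(frames_l) + 1L
      frames_l[[k]] <- fr[keep]; rows_l[[k]] <- r[keep]
      cols_l[[k]] <- cl[keep]; tbins_l[[k]] <- tb[keep]
    }
  })
  ev <- data.frame(frame = as.integer(unlist(frames_l)),
                   row = as.integer(unlist(rows_l)),
                   col = as.integer(unlist(cols_l)),
                   tbin = as.integer(unlist(tbins_l)))
  if (nrow(ev))
    ev <- ev[order(ev$frame, ev$row, ev$col, ev$tbin), , drop = FALSE]
  rownames(ev) <- NULL
  new("PhotonEventStream", events = ev, height = H, width = W,
      n_bins = B, period_ns = scene@period_ns,
      frame_rate_hz = scene@frame_rate_hz)
}

#' Simulate a single pooled intensity image
#'
#' Convenience generator for segmentation benchmarks: the expected
#' per-pixel photon count of the full acquisition window (nuclei plus
#' uniform background) with Poisson counting noise, skipping the
#' event-level simulation.
#'
#' @param scene a [Scene-class].
#' @param seed integer seed.
#' @return numeric `height x width` matrix of photon counts.
#' @export
simulateIntensityImage <- function(scene, seed = 1L) {
  lam <- expectedSignalImage(scene) +
    scene@background_rate * scene@n_frames
  withSeed(substreamSeed(seed, "intensity"), {
    matrix(rpois(length(lam), as.vector(lam)), scene@height, scene@width)
  })
}
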