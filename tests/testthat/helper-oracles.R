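# Shared fixtures and independent oracles used across test files.

# Draw a Poisson-multinomial TCSPC histogram with `n` photons from a
# per-bin probability curve.
sampleHist <- function(n, curve, period_ns = 12.5) {
  tb <- sample.int(length(curve), n, replace = TRUE, prob = curve)
  decayHistogram(tabulate(tb, nbins = length(curve)), period_ns = period_ns)
}

# Brute-force NCC registration: explicit normalized cross-correlation
# sums over every candidate shift, written independently of the package
# implementation.
bruteForceNCC <- function(frame, template, origin, search) {
  th <- nrow(template); tw <- ncol(template)
  tm <- mean(template)
  tnum <- template - tm
  best <- c(NA, NA); best_score <- -Inf; best_mag <- Inf
  for (dr in -search:search) {
    for (dc in -search:search) {
      rr <- origin[1] + dr; cc <- origin[2] + dc
      if (rr < 1 || cc < 1 || rr + th - 1 > nrow(frame) ||
          cc + tw - 1 > ncol(frame)) next
      patch <- frame[rr:(rr + th - 1), cc:(cc + tw - 1)]
      pm <- mean(patch)
      num <- sum(tnum * (patch - pm))
      den <- sqrt(sum(tnum^2) * sum((patch - pm)^2))
      score <- if (den == 0) 0 else num / den
      mag <- dr^2 + dc^2
      if (score > best_score + 1e-12 ||
          (abs(score - best_score) <= 1e-12 && mag < best_mag)) {
        best_score <- score; best <- c(dr, dc); best_mag <- mag
      }
    }
  }
  list(shift = best, score = best_score)
}

# Brute-force population-fraction fit: likelihood evaluated on an f grid
# (step 1e-3) for fixed lifetime components, no optimizer involved.
gridFretFit <- function(counts, tau_long, tau_short, period_ns = 12.5) {
  n <- length(counts)
  d_l <- expectedDecay(list(c(1, tau_long)), NULL, period_ns, n)
  d_s <- expectedDecay(list(c(1, tau_short)), NULL, period_ns, n)
  fs <- seq(0, 1, by = 1e-3)
  ll <- vapply(fs, function(f) {
    w <- f * tau_short / (f * tau_short + (1 - f) * tau_long)
    p <- w * d_s + (1 - w) * d_l
    sum(counts * log(pmax(p, 1e-300)))
  }, numeric(1))
  fs[which.max(ll)]
}

# Hand-computed Welch statistic, Welch-Satterthwaite df and two-tailed p.
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Greedy nearest-centroid matching between truth and detected nuclei.
matchCentroids <- function(truth_rc, est_rc, max_dist = 3) {
  matches <- data.frame(truth = integer(0), est = integer(0),
                        dist = numeric(0))
  if (nrow(truth_rc) == 0 || nrow(est_rc) == 0) return(matches)
  d <- sqrt(outer(truth_rc[, 1], est_rc[, 1], "-")^2 +
              outer(truth_rc[, 2], est_rc[, 2], "-")^2)
  while (TRUE) {
    i <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[i[1], i[2]] > max_dist) break
    matches <- rbind(matches, data.frame(truth = i[1], est = i[2],
                                         dist = d[i[1], i[2]]))
    d[i[1], ] <- Inf; d[, i[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  matches
}

# Binary disc mask helper for segmentation fixtures.
discMask <- function(H, W, cr, cc, r) {
  d <- sqrt(outer((1:H - cr)^2, (1:W - cc)^2, "+"))
  d <= r
}

# Small event stream fixture used by io / gating tests.
toyStream <- function() {
  ev <- data.frame(frame = c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L),
                   row = c(1L, 2L, 3L, 1L, 4L, 0L, 2L, 5L, 3L, 4L),
                   col = c(0L, 1L, 2L, 3L, 4L, 5L, 0L, 1L, 2L, 3L),
                   tbin = c(0L, 5L, 10L, 3L, 7L, 1L, 2L, 15L, 8L, 4L))
  photonEventStream(ev, height = 6L, width = 6L, n_bins = 16L,
                    period_ns = 12.5, frame_rate_hz = 8.5)
}

# Dense synthetic logistic-saturation calibration used by LUT tests.
denseLogisticCalib <- function() {
  gen <- function(C) 0.7 * C / (C + 1)
  kn <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16)
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(concentration_uM = kn,
                       nonfret_fraction = 1 - gen(kn)),
            tmp, row.names = FALSE)
  list(calib = readCalibrationTable(tmp), gen = gen, c_max = 16)
}
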