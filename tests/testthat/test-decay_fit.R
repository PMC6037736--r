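test_that("expected decay matches closed forms", {
  # period >> tau: bins proportional to exp(-t_i / tau)
  n <- 200; period <- 100; tau <- 2000
  p <- expectedDecay(list(c(1, tau)), NULL, period, n)
  t_lo <- (0:(n - 1)) * period / n
  ref <- exp(-t_lo / (tau / 1000))
  ratio <- p / ref
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-6)
  expect_equal(sum(p), 1)

  # incomplete decay: tau = period lifts every bin by 1/(1 - e^(-T/tau))
  # relative to the naive (infinite-window) exponential mass
  n <- 64; period <- 2.5; tau <- 2500
  p <- expectedDecay(list(c(1, tau)), NULL, period, n)
  edges <- seq(0, period, length.out = n + 1)
  naive <- exp(-edges[-(n + 1)] / 2.5) - exp(-edges[-1] / 2.5)
  expect_equal(p / naive, rep(1 / (1 - exp(-1)), n))

  # mixtures are linear in the component curves
  pa <- expectedDecay(list(c(1, 2330)), NULL, 12.5, 256)
  pb <- expectedDecay(list(c(1, 770)), NULL, 12.5, 256)
  pm <- expectedDecay(list(c(0.5, 2330), c(0.5, 770)), NULL, 12.5, 256)
  expect_equal(pm, 0.5 * pa + 0.5 * pb)

  # remainder goes to a uniform background
  pu <- expectedDecay(list(c(0.6, 2330)), NULL, 12.5, 256)
  expect_equal(pu, 0.6 * pa + 0.4 / 256)

  expect_error(expectedDecay(list(c(1, -5))), "lifetime")
  expect_error(expectedDecay(list(c(0.7, 100), c(0.6, 200))), "sum")
})

test_that("IRF convolution shifts and broadens the model", {
  n <- 256
  irf <- irfProfile(dnorm(seq(0, 12.5, length.out = n), mean = 1, sd = 0.1))
  p <- expectedDecay(list(c(1, 2000)), irf, 12.5, n)
  expect_equal(sum(p), 1)
  # peak sits near the IRF center, not at bin 1
  expect_gt(which.max(p), 15)
  expect_error(irfProfile(c(-1, 2)), "non-negative")
})

test_that("background correction subtracts the blank and propagates variance", {
  raw <- decayHistogram(c(10, 8, 6, 4, 3, 2, 1, 1))
  zero <- decayHistogram(rep(0, 8))
  corr <- correctBackground(raw, zero)
  expect_equal(decayCounts(corr), decayCounts(raw))
  expect_equal(corr@variance, decayCounts(raw))

  self <- correctBackground(raw, raw)
  expect_equal(decayCounts(self), rep(0, 8))
  expect_equal(self@variance, 2 * decayCounts(raw))

  expect_error(correctBackground(raw, decayHistogram(rep(1, 6))), "grid")
})

test_that("background correction removes the lifetime bias of a 30% blank", {
  set.seed(61)
  n <- 256; tau <- 2300
  p <- expectedDecay(list(c(1, tau)), NULL, 12.5, n)
  raw <- decayHistogram(rpois(n, 7e4 * p + 3e4 / n))
  blank <- decayHistogram(rpois(n, rep(3e4 / n, n)))
  naive <- fitSingleExponential(raw, background = "none")
  expect_gt(abs(naive@tau_ps - tau) / tau, 0.10)
  corrected <- fitSingleExponential(correctBackground(raw, blank),
                                    background = "none")
  expect_lt(abs(corrected@tau_ps - tau) / tau, 0.02)
})

test_that("single-exponential fits are self-consistent and unbiased", {
  # noiseless curve recovers tau to 0.1%
  p <- expectedDecay(list(c(1, 2330)), NULL, 12.5, 256)
  fit <- fitSingleExponential(decayHistogram(1e6 * p), background = "none")
  expect_lt(abs(fit@tau_ps - 2330) / 2330, 1e-3)
  expect_true(fit@converged)

  # free background recovers both components
  pb <- 0.9 * p + 0.1 / 256
  fitb <- fitSingleExponential(decayHistogram(1e6 * pb))
  expect_lt(abs(fitb@tau_ps - 2330) / 2330, 1e-3)
  expect_equal(fitb@background_level, 1e6 * 0.1 / 256, tolerance = 0.05)

  # Monte-Carlo bias at 1e4 photons under the delta IRF stays below 1%
  set.seed(62)
  taus <- replicate(60, {
    h <- sampleHist(1e4, p)
    fitSingleExponential(h, background = "none")@tau_ps
  })
  expect_lt(abs(mean(taus) - 2330) / 2330, 0.01)
})

test_that("relative precision at 100 photons sits near the 1/sqrt(N) budget", {
  set.seed(63)
  p <- expectedDecay(list(c(1, 2300)), NULL, 12.5, 256)
  taus <- replicate(250, {
    h <- sampleHist(100, p)
    fitSingleExponential(h, background = "none")@tau_ps
  })
  cv <- 100 * sd(taus) / mean(taus)
  expect_gt(cv, 7); expect_lt(cv, 14)
})

test_that("distinct dye lifetimes are resolved and ordered", {
  set.seed(64)
  p1 <- expectedDecay(list(c(1, 1700)), NULL, 12.5, 256)
  p2 <- expectedDecay(list(c(1, 4000)), NULL, 12.5, 256)
  f1 <- fitSingleExponential(sampleHist(2e4, p1), background = "none")
  f2 <- fitSingleExponential(sampleHist(2e4, p2), background = "none")
  expect_lt(f1@tau_ps, f2@tau_ps)
  expect_equal(f1@tau_ps, 1700, tolerance = 0.05)
  expect_equal(f2@tau_ps, 4000, tolerance = 0.05)
})

test_that("fixed-lifetime fraction fits match the likelihood-grid oracle", {
  set.seed(65)
  mkmix <- function(f, n) {
    w <- f * 770 / (f * 770 + (1 - f) * 2460)
    p <- expectedDecay(list(c(1 - w, 2460), c(w, 770)), NULL, 12.5, 256)
    sampleHist(n, p)
  }
  h <- mkmix(0.5, 1e5)
  fit <- fitGlobalBiexp(list(h), tau_long_ps = 2460, tau_short_ps = 770,
                        background = "none")
  expect_equal(fretFractions(fit), 0.5, tolerance = 0.04)
  oracle <- gridFretFit(decayCounts(h), 2460, 770)
  expect_lt(abs(fretFractions(fit) - oracle), 2e-3)

  # null case: mono-exponential data at tau_long gives f near zero
  p_null <- expectedDecay(list(c(1, 2460)), NULL, 12.5, 256)
  hs <- lapply(1:5, function(i) sampleHist(3e5, p_null))
  fit0 <- fitGlobalBiexp(hs, tau_long_ps = 2460, tau_short_ps = 770,
                         background = "none")
  expect_true(all(fretFractions(fit0) <= 0.02))
})

test_that("the global short-lifetime profile recovers shared kinetics", {
  set.seed(66)
  fs <- seq(0.15, 0.55, length.out = 8)
  hs <- lapply(fs, function(f) {
    w <- f * 770 / (f * 770 + (1 - f) * 2460)
    p <- expectedDecay(list(c(1 - w, 2460), c(w, 770)), NULL, 12.5, 256)
    sampleHist(3e4, p)
  })
  fit <- fitGlobalBiexp(hs, tau_long_ps = 2460, background = "none")
  expect_true(fit@tau_short_fitted)
  expect_equal(shortLifetime(fit), 770, tolerance = 0.05)
  expect_equal(fretFractions(fit), fs, tolerance = 0.05)
  expect_error(fitGlobalBiexp(hs[1], tau_long_ps = 2460), ">= 2")
})

test_that("degenerate lifetimes raise an explanatory error", {
  set.seed(67)
  p <- expectedDecay(list(c(1, 2456)), NULL, 12.5, 256)
  hs <- lapply(1:3, function(i) sampleHist(3e5, p))
  expect_error(
    fitGlobalBiexp(hs, tau_long_ps = 2460, background = "none",
                   tau_short_range_ps = c(100, 2455)),
    "degenerate")
})

test_that("mean lifetime weighting follows the amplitude formula", {
  expect_equal(intensityWeightedMeanLifetime(c(1, 0), c(2330, 770)), 2330)
  # (0.5 * 2330^2 + 0.5 * 770^2) / (0.5 * 2330 + 0.5 * 770)
  expect_equal(intensityWeightedMeanLifetime(c(0.5, 0.5), c(2330, 770)),
               3010900 / 1550)
  expect_equal(intensityWeightedMeanLifetime(c(0.3, 0.7), c(1500, 1500)),
               1500)
  expect_error(intensityWeightedMeanLifetime(c(0, 0), c(1, 2)), "zero")
  # increasing FRET fraction strictly lowers the fitted mean lifetime
  taum <- vapply(seq(0.1, 0.9, by = 0.1), function(f) {
    w <- f * 770 / (f * 770 + (1 - f) * 2460)
    p <- expectedDecay(list(c(1 - w, 2460), c(w, 770)), NULL, 12.5, 256)
    fit <- fitGlobalBiexp(list(decayHistogram(1e6 * p)),
                          tau_long_ps = 2460, tau_short_ps = 770,
                          background = "none")
    meanLifetimes(fit)
  }, numeric(1))
  expect_true(all(diff(taum) < 0))
  expect_true(all(taum >= 770 & taum <= 2460))
})

test_that("the IRF temporal offset is recovered from a reference dye", {
  set.seed(68)
  n <- 256
  irf0 <- irfProfile(dnorm(seq(0, 12.5, length.out = n), 0.8, 0.08))
  shifted <- irf0; shifted@temporal_offset_ns <- 0.4
  p <- expectedDecay(list(c(1, 4000)), shifted, 12.5, n)
  ref <- sampleHist(2e5, p)
  est <- estimateIrfOffset(ref, 4000, irf0)
  expect_equal(est$offset_ns, 0.4, tolerance = 0.05)
  expect_false(est$at_boundary)
  expect_equal(est$irf@temporal_offset_ns, est$offset_ns)

  p0 <- expectedDecay(list(c(1, 4000)), irf0, 12.5, n)
  est0 <- estimateIrfOffset(sampleHist(2e5, p0), 4000, irf0)
  expect_lte(abs(est0$offset_ns), 12.5 / n / 2 + 1e-9)

  big <- irf0; big@temporal_offset_ns <- 0.9
  pb <- expectedDecay(list(c(1, 4000)), big, 12.5, n)
  expect_warning(
    estb <- estimateIrfOffset(sampleHist(2e5, pb), 4000, irf0,
                              offset_range_ns = c(-0.5, 0.5)),
    "boundary")
  expect_true(estb$at_boundary)
})

test_that("precision scales as the square root of the photon count", {
  set.seed(69)
  p <- expectedDecay(list(c(1, 2300)), NULL, 12.5, 256)
  cvAt <- function(N, reps) {
    taus <- replicate(reps, fitSingleExponential(sampleHist(N, p),
                                                 background = "none")@tau_ps)
    sd(taus) / mean(taus)
  }
  cv100 <- cvAt(100, 200)
  cv400 <- cvAt(400, 200)
  expect_equal(cv400 / cv100, 0.5, tolerance = 0.15)
})
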