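test_that("scene construction is deterministic and uses acquisition defaults", {
  s1 <- makeScene(seed = 5)
  s2 <- makeScene(seed = 5)
  expect_identical(sceneNuclei(s1), sceneNuclei(s2))
  expect_identical(s1@height, 118L)
  expect_identical(s1@width, 172L)
  expect_identical(s1@n_frames, 85L)
  expect_identical(s1@n_bins, 256L)
  expect_equal(s1@frame_rate_hz, 8.5)
  expect_equal(s1@period_ns, 12.5)
  s3 <- makeScene(seed = 6)
  expect_false(identical(sceneNuclei(s1), sceneNuclei(s3)))
})

test_that("scene validation rejects out-of-range parameters by name", {
  nuc <- data.frame(center_row = 20, center_col = 20, radius = 0,
                    brightness = 700, fret_fraction = 0.3, dox_uM = 1)
  expect_error(makeScene(nuclei = nuc), "radius")
  nuc$radius <- 5; nuc$fret_fraction <- 1.5
  expect_error(makeScene(nuclei = nuc), "fret_fraction")
  nuc$fret_fraction <- 0.3; nuc$center_row <- 500
  expect_error(makeScene(nuclei = nuc), "bounds")
  expect_error(makeScene(height = 0), "height|dimensions")
})

test_that("motion trajectories respect bounds and distortion flags", {
  sc <- makeScene(n_frames = 1000L, n_nuclei = 2L, seed = 1)
  tr <- simulateMotion(sc, amplitude = 5, distortion_prob = 0.3, seed = 2)
  expect_equal(nrow(tr), 1000L)
  expect_lte(max(abs(tr$d_row)), 5)
  expect_lte(max(abs(tr$d_col)), 5)
  expect_gt(mean(tr$distorted), 0.25)
  expect_lt(mean(tr$distorted), 0.35)
  # distorted frames always carry a substantial warp
  expect_true(all(abs(tr$warp_t_row[tr$distorted]) >= 4))
  expect_true(all(tr$warp_t_row[!tr$distorted] == 0))

  still <- simulateMotion(sc, amplitude = 0, distortion_prob = 0, seed = 2)
  expect_true(all(still$d_row == 0L & still$d_col == 0L))
  expect_false(any(still$distorted))
  allwarp <- simulateMotion(sc, amplitude = 0, distortion_prob = 1, seed = 2)
  expect_true(all(allwarp$distorted))
  expect_error(simulateMotion(sc, amplitude = -1), "amplitude")
  expect_error(simulateMotion(sc, distortion_prob = 2), "distortion_prob")
})

test_that("photon sampling is deterministic and respects emptiness", {
  sc <- makeScene(height = 40L, width = 40L, n_nuclei = 1L,
                  radius_range = c(5, 5), background_rate = 0.05, seed = 3)
  tr <- simulateMotion(sc, seed = 3)
  s1 <- samplePhotonEvents(sc, tr, seed = 9)
  s2 <- samplePhotonEvents(sc, tr, seed = 9)
  expect_identical(eventTable(s1), eventTable(s2))

  empty_scene <- makeScene(height = 30L, width = 30L,
                           nuclei = data.frame(center_row = numeric(0),
                                               center_col = numeric(0),
                                               radius = numeric(0),
                                               brightness = numeric(0),
                                               fret_fraction = numeric(0),
                                               dox_uM = numeric(0)),
                           background_rate = 0, seed = 1)
  expect_equal(nPhotons(samplePhotonEvents(empty_scene, seed = 1)), 0L)

  bad_traj <- tr[1:10, ]
  expect_error(samplePhotonEvents(sc, bad_traj, seed = 1), "trajectory")
})

test_that("per-pixel counts follow the configured Poisson photon budget", {
  nuc <- data.frame(center_row = 30, center_col = 30, radius = 12,
                    brightness = 700, fret_fraction = 0.3, dox_uM = 1)
  sc <- makeScene(height = 60L, width = 60L, nuclei = nuc,
                  background_rate = 0, edge_sigma = 0, seed = 4)
  st <- samplePhotonEvents(sc, seed = 4)
  img <- intensityImage(st)
  core <- discMask(60, 60, 30, 30, 9)  # interior, away from the rim
  m <- mean(img[core])
  se <- sd(img[core]) / sqrt(sum(core))
  expect_lt(abs(m - 700), 3 * se + 1e-9)
  # photon conservation: events = per-pixel image total
  expect_equal(sum(img), nPhotons(st))
})

test_that("background pixels are Poisson with uniform micro-times", {
  sc <- makeScene(height = 40L, width = 40L,
                  nuclei = data.frame(center_row = numeric(0),
                                      center_col = numeric(0),
                                      radius = numeric(0),
                                      brightness = numeric(0),
                                      fret_fraction = numeric(0),
                                      dox_uM = numeric(0)),
                  background_rate = 0.5, n_frames = 40L, seed = 8)
  st <- samplePhotonEvents(sc, seed = 8)
  img <- intensityImage(st)
  lambda <- 0.5 * 40
  # chi-square dispersion test over 1600 pixels at alpha = 0.01
  x2 <- sum((img - lambda)^2 / lambda)
  p <- pchisq(x2, df = length(img), lower.tail = FALSE)
  expect_gt(min(p, 1 - p), 0.005)
  # micro-time marginal uniform over bins
  tb <- tabulate(eventTable(st)$tbin + 1L, nbins = 256)
  gof <- chisq.test(tb, p = rep(1 / 256, 256))
  expect_gt(gof$p.value, 0.01)
})

test_that("FRET-free, drug-free nuclei decay mono-exponentially at tau_long", {
  nuc <- data.frame(center_row = 25, center_col = 25, radius = 10,
                    brightness = 900, fret_fraction = 0, dox_uM = 0)
  sc <- makeScene(height = 50L, width = 50L, nuclei = nuc,
                  background_rate = 0, seed = 10)
  st <- samplePhotonEvents(sc, decay = decayModel(tau_long_ps = 2460),
                           seed = 10)
  tb <- tabulate(eventTable(st)$tbin + 1L, nbins = 256)
  p_model <- expectedDecay(list(c(1, 2460)), NULL, 12.5, 256)
  gof <- chisq.test(tb, p = p_model)
  expect_gt(gof$p.value, 0.01)
})

test_that("static acquisitions give exchangeable frames", {
  nuc <- data.frame(center_row = 20, center_col = 20, radius = 8,
                    brightness = 680, fret_fraction = 0.2, dox_uM = 0.5)
  sc <- makeScene(height = 40L, width = 40L, nuclei = nuc,
                  background_rate = 0.1, n_frames = 60L, seed = 12)
  st <- samplePhotonEvents(sc, seed = 12)
  per_frame <- tabulate(eventTable(st)$frame + 1L, nbins = 60)
  lambda <- mean(per_frame)
  x2 <- sum((per_frame - lambda)^2 / lambda)
  p <- pchisq(x2, df = 59, lower.tail = FALSE)
  expect_gt(min(p, 1 - p), 0.005)
})
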