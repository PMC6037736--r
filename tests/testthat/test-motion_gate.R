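test_that("frame budget follows the floor rule", {
  expect_identical(framesInWindow(10, 8.5), 85L)
  expect_identical(framesInWindow(1, 8.5), 8L)
  expect_identical(framesInWindow(0.117, 8.5), 0L)
  expect_error(framesInWindow(0, 8.5), "duration")
  expect_error(framesInWindow(10, -1), "frame_rate")
})

test_that("registration recovers exact shifts and scores", {
  set.seed(21)
  ref <- matrix(runif(40 * 40), 40, 40)
  tpl <- ref[11:30, 11:30]
  same <- registerFrame(ref, tpl, c(11, 11), search_range = 6)
  expect_identical(same$shift, c(0L, 0L))
  expect_equal(same$score, 1, tolerance = 1e-6)

  # frame content displaced by (3, -2), zero-filled borders
  shifted <- matrix(0, 40, 40)
  shifted[4:40, 1:38] <- ref[1:37, 3:40]
  rec <- registerFrame(shifted, tpl, c(11, 11), search_range = 6)
  expect_identical(rec$shift, c(3L, -2L))
  expect_gt(rec$score, 0.999)

  flat <- matrix(5, 20, 20)
  expect_error(registerFrame(ref, flat[1:5, 1:5], c(11, 11)), "variance")
})

test_that("registration matches the brute-force NCC oracle on small images", {
  set.seed(22)
  for (i in 1:8) {
    frame <- matrix(runif(32 * 32), 32, 32)
    tpl <- frame[9:24, 9:24]
    dr <- sample(-4:4, 1); dc <- sample(-4:4, 1)
    moved <- matrix(0, 32, 32)
    src_r <- (1:32) - dr; src_c <- (1:32) - dc
    ok_r <- src_r >= 1 & src_r <= 32; ok_c <- src_c >= 1 & src_c <= 32
    moved[ok_r, ok_c] <- frame[src_r[ok_r], src_c[ok_c]]
    got <- registerFrame(moved, tpl, c(9, 9), search_range = 6)
    oracle <- bruteForceNCC(moved, tpl, c(9, 9), 6)
    expect_identical(got$shift, as.integer(oracle$shift))
    expect_equal(got$score, oracle$score, tolerance = 1e-12)
  }
})

test_that("pure-noise frames score below the gate", {
  set.seed(23)
  nuc <- data.frame(center_row = c(15, 30), center_col = c(15, 30),
                    radius = 6, brightness = 700,
                    fret_fraction = 0.3, dox_uM = 1)
  sc <- makeScene(height = 45L, width = 45L, nuclei = nuc, seed = 23)
  st <- samplePhotonEvents(sc, seed = 23)
  ref <- intensityImage(st, frame = 0)
  tpl <- ref[8:38, 8:38]
  noise <- matrix(rpois(45 * 45, mean(ref)), 45, 45)
  got <- registerFrame(noise, tpl, c(8, 8), search_range = 5)
  expect_lt(got$score, 0.9)
})

test_that("gating and accumulation conserve photons", {
  st <- toyStream()
  nf <- 4L
  rep_all <- new("AlignmentReport",
                 frames = data.frame(frame = 0:3, d_row = 0L, d_col = 0L,
                                     score = 1, accepted = TRUE),
                 template_region = c(1L, 1L, 3L, 3L), threshold = 0.9,
                 search_range = 15L, reference_frame = 0L)
  pooled <- gateAndAccumulate(st, rep_all)
  expect_equal(intensityImage(pooled), intensityImage(st))
  expect_equal(nPhotons(pooled), nPhotons(st))
  expect_identical(pooled@n_frames_used, 4L)

  rep_none <- rep_all
  rep_none@frames$accepted <- FALSE
  rep_none@frames$score <- 0
  expect_warning(empty <- gateAndAccumulate(st, rep_none), "rejected")
  expect_equal(nPhotons(empty), 0)
  expect_identical(empty@n_frames_used, 0L)

  # shifts push border events off-grid; dropped events are counted
  rep_shift <- rep_all
  rep_shift@frames$d_row <- c(0L, 5L, 0L, 0L)
  suppressMessages(pooled2 <- gateAndAccumulate(st, rep_shift))
  expect_equal(nPhotons(pooled2) + pooled2@n_dropped_oob, nPhotons(st))
})

test_that("aligned accumulation undoes known rigid motion", {
  nuc <- data.frame(center_row = c(20, 20, 42), center_col = c(18, 44, 30),
                    radius = 6, brightness = 800,
                    fret_fraction = 0.3, dox_uM = 1)
  # zero background: uniform instrument background is not tied to tissue
  # motion, so only nucleus photons are expected to map back exactly
  sc <- makeScene(height = 60L, width = 60L, nuclei = nuc,
                  background_rate = 0, seed = 31)
  tr <- simulateMotion(sc, amplitude = 4, distortion_prob = 0, seed = 31)
  st <- samplePhotonEvents(sc, tr, seed = 31)
  rep <- alignFrames(st, search_range = 8)
  fr <- alignmentFrames(rep)
  expect_true(all(fr$accepted))
  # recovered shifts equal the simulated walk, relative to the reference
  ref_i <- rep@reference_frame + 1L
  expect_equal(fr$d_row, tr$d_row - tr$d_row[ref_i])
  expect_equal(fr$d_col, tr$d_col - tr$d_col[ref_i])
  suppressMessages(pooled <- gateAndAccumulate(st, rep))

  st0 <- samplePhotonEvents(sc, NULL, seed = 31)
  img0 <- intensityImage(st0)
  img <- intensityImage(pooled)
  # the pooled grid sits at the reference frame's walk position:
  # pooled[r, c] = static[r - d_ref_r, c - d_ref_c] away from borders
  b <- 10
  core <- (1 + b):(60 - b)
  expect_equal(img[core, core],
               img0[core - tr$d_row[ref_i], core - tr$d_col[ref_i]])
})

test_that("lowering the gate threshold never loses frames", {
  sc <- makeScene(height = 60L, width = 60L, n_nuclei = 3L,
                  radius_range = c(5, 7), seed = 33)
  tr <- simulateMotion(sc, amplitude = 3, distortion_prob = 0.3, seed = 33)
  st <- samplePhotonEvents(sc, tr, seed = 33)
  r09 <- alignFrames(st, threshold = 0.9, search_range = 8)
  r08 <- alignFrames(st, threshold = 0.8, search_range = 8)
  a09 <- alignmentFrames(r09)$accepted
  a08 <- alignmentFrames(r08)$accepted
  expect_true(all(a08[a09]))
  expect_gte(sum(a08), sum(a09))
})

test_that("distorted frames are rejected at the default gate", {
  tot_d <- 0L; rej_d <- 0L
  for (sd in c(7L, 11L)) {
    sc <- makeScene(seed = sd)
    tr <- simulateMotion(sc, seed = sd)
    st <- samplePhotonEvents(sc, tr, seed = sd)
    fr <- alignmentFrames(alignFrames(st))
    tot_d <- tot_d + sum(tr$distorted)
    rej_d <- rej_d + sum(!fr$accepted[tr$distorted])
    expect_true(all(fr$accepted[!tr$distorted]))
  }
  expect_gte(rej_d / tot_d, 0.95)
})
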