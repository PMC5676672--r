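test_that("pit finding matches a brute-force scan on constructed spectra", {
  binW <- 0.045
  ## flat spectrum: no candidates
  flat <- spectrumFromH(rep(1.9, 200), binW)
  expect_identical(nrow(findEntropyPits(flat)), 0L)

  ## one rectangular dip at bins 64-72
  H <- rep(1.9, 200) + rnorm(200, sd = 1e-3)
  H[64:72] <- 1.2
  H[68] <- 1.1
  sp <- spectrumFromH(H, binW)
  pits <- findEntropyPits(sp)
  ## brute-force oracle: recompute threshold and scan runs naively
  beyond <- sp@rangeAxisM > 1
  thr <- median(H[beyond]) - 3 * mad(H[beyond])
  below <- which(H < thr & beyond)
  expect_identical(below, 64:72)
  expect_identical(nrow(pits), 1L)
  expect_equal(pits$lo_m, 64 * binW - binW / 2)
  expect_equal(pits$hi_m, 72 * binW + binW / 2)
  expect_equal(pits$range_m, 68 * binW)   # minimum inside
  expect_equal(pits$n_bins, 9L)

  ## two dips separated by a supra-threshold gap: two pits
  H2 <- rep(1.9, 200) + rnorm(200, sd = 1e-3)
  H2[60:68] <- 1.2
  H2[120:128] <- 1.3
  expect_identical(nrow(findEntropyPits(spectrumFromH(H2, binW))), 2L)

  ## too few bins beyond the blind range errors
  tiny <- new("EntropySpectrum", H = rep(1, 10), rangeAxisM = seq(0.1, 1, 0.1),
              zeroEnergy = logical(10), params = list())
  expect_error(findEntropyPits(tiny), "at least 8")
})

test_that("width gating and ghost attribution classify pits as specified", {
  binW <- 0.045
  H <- rep(1.9, 200) + rnorm(200, sd = 1e-3)
  H[65:73] <- 1.2        # 9 bins ~ 0.405 m at ~3 m: a torso -> accepted
  H[79:80] <- 1.2        # 2 bins ~ 0.09 m just behind -> ghost
  H[150:183] <- 1.2      # 34 bins ~ 1.5 m isolated -> width rejection
  rep <- classifyPits(findEntropyPits(spectrumFromH(H, binW)))
  d <- detections(rep)
  expect_identical(d$status, c("accepted", "rejected_ghost", "rejected_width"))
  acc <- detections(rep, "accepted")
  expect_equal(acc$width_m, 9 * binW)
  ## every accepted pit minimum is below the threshold
  expect_true(all(acc$h_min < rep@threshold))
  ## accepted pits lie beyond the blind range
  expect_true(all(acc$lo_m > 1))
})

test_that("detection is invariant to adding a constant to the spectrum", {
  set.seed(23)
  H <- rep(1.85, 150) + rnorm(150, sd = 0.01)
  H[70:78] <- 0.6
  r1 <- classifyPits(findEntropyPits(spectrumFromH(H)))
  r2 <- classifyPits(findEntropyPits(spectrumFromH(H + 5)))
  expect_equal(detections(r1)[names(detections(r1)) != "h_min"],
               detections(r2)[names(detections(r2)) != "h_min"])
})

test_that("power profile reflects scene energetics, baseline misses shadowed targets", {
  ## zero matrix -> zero profile
  mz <- echoMatrix(matrix(0, 8, 64), fastDtNs = 1, slowFsHz = 64)
  expect_true(all(powerSpectrumProfile(mz)$power == 0))
  expect_error(powerSpectrumProfile(mz, c(0.1, 40)), "Nyquist")

  ## shadowed scene: single baseline peak at the near target
  mShad <- preprocessEcho(simulateScene(studyScene(rangeB = 6, seed = 31L)))
  pk <- findPowerPeaks(powerSpectrumProfile(mShad))
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$range_m, 3, tolerance = 0.05)

  ## no-shadow scene: two local maxima in the profile, the farther smaller
  mopen <- preprocessEcho(simulateScene(studyScene(rangeB = 6, angleB = 90,
                                                   seed = 31L)))
  pr <- powerSpectrumProfile(mopen)
  nearPk <- max(pr$power[abs(pr$range_m - 3) < 0.3])
  farPk <- max(pr$power[abs(pr$range_m - 6) < 0.3])
  floorPwr <- median(pr$power[pr$range_m > 1])
  expect_gt(farPk, 20 * floorPwr)   # a clear local maximum
  expect_gt(nearPk, farPk)          # attenuation with range
})
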