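test_that("simulated matrix has the configured dimensions and range axis", {
  cfg <- sceneConfig(nFast = 2048L, slowFsHz = 64, durationS = 32,
                     wallAmp = 0, noiseSigma = 0)
  m <- simulateScene(cfg)
  expect_identical(dim(m), c(2048L, 2048L))
  r <- rangeAxis(m)
  expect_true(all(diff(r) > 0))
  expect_equal(max(r), 9.0)            # 60 ns two-way -> 9 m
  expect_equal(axisType(m), "slow_time")
})

test_that("target-free unit-noise scene has white rows; sigma scales exactly", {
  cfg <- smallScene(wallAmp = 0, noiseSigma = 1, seed = 11L)
  m <- echoData(simulateScene(cfg))
  rowMu <- rowMeans(m)
  rowVar <- apply(m, 1L, var)
  ## Monte-Carlo bands for n = 512 per row
  expect_lt(max(abs(rowMu)), 5 / sqrt(ncol(m)))
  expect_true(all(rowVar > 0.7 & rowVar < 1.35))
  ## doubling sigma doubles every sample exactly (same seeded draws)
  m2 <- echoData(simulateScene(smallScene(wallAmp = 0, noiseSigma = 2,
                                          seed = 11L)))
  expect_equal(m2, 2 * m, tolerance = 1e-12)
})

test_that("noiseless target row peaks at the respiration frequency", {
  cfg <- smallScene(targets = list(targetSpec(3, respFreqHz = 0.25)),
                    wallAmp = 0, noiseSigma = 0)
  m <- simulateScene(cfg)
  row <- echoData(m)[which.min(abs(rangeAxis(m) - 3)), ]
  expect_equal(fftPeakHz(row, slowRate(m)), 0.25, tolerance = 1e-6)
})

test_that("same seed gives a bit-identical matrix", {
  cfg <- smallScene(targets = list(targetSpec(2)), seed = 99L)
  expect_identical(echoData(simulateScene(cfg)), echoData(simulateScene(cfg)))
})

test_that("noiseless scenes superpose and shadowing scales amplitudes exactly", {
  tA <- targetSpec(3, respFreqHz = 0.3)
  tB <- targetSpec(6, respFreqHz = 0.25)
  base <- list(nFast = 512L, durationS = 8, wallAmp = 0, noiseSigma = 0)
  mk <- function(tg) do.call(sceneConfig, c(list(targets = tg), base))
  ## disable the shadow geometrically: B far off the cone
  tBoff <- targetSpec(6, angleDeg = 90, respFreqHz = 0.25)
  mAB <- echoData(simulateScene(mk(list(tA, tBoff))))
  mA <- echoData(simulateScene(mk(list(tA))))
  mB <- echoData(simulateScene(mk(list(tBoff))))
  expect_equal(mAB, mA + mB, tolerance = 1e-12)

  ## shadowed B = shadowAtten x unshadowed B, exactly, in the noiseless case
  att <- 0.25
  mShad <- echoData(simulateScene(do.call(sceneConfig,
    c(list(targets = list(tA, tB), shadowAtten = att), base))))
  mBon <- echoData(simulateScene(mk(list(tB))))
  expect_equal(mShad - mA, att * mBon, tolerance = 1e-12)
})

test_that("shadow factor follows the cone geometry", {
  cfg <- sceneConfig(shadowHalfAngleDeg = 20, shadowAtten = 0.1)
  front <- targetSpec(3, angleDeg = 0)
  expect_equal(shadowFactor(front, targetSpec(6, angleDeg = 0), cfg), 0.1)
  expect_equal(shadowFactor(front, targetSpec(6, angleDeg = 30), cfg), 1.0)
  expect_equal(shadowFactor(front, targetSpec(6, angleDeg = 10), cfg), 0.1)
  ## boundary bearing counts as inside the cone
  expect_equal(shadowFactor(front, targetSpec(6, angleDeg = 20), cfg), 0.1)
  ## a nearer target is never shadowed
  expect_equal(shadowFactor(front, targetSpec(2, angleDeg = 0), cfg), 1.0)
})

test_that("coincident targets are rejected with a configuration error", {
  cfg <- smallScene(targets = list(targetSpec(3), targetSpec(3)))
  expect_error(simulateScene(cfg), class = "bioradar_config_error")
})
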