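test_that("subband energies are squared-coefficient sums, windowed and normalised", {
  ## single band with coefficients [3]: energy 9 in both modes
  d <- new("WaveletDecomposition",
           coeffs = list(D1 = 3, A1 = 0), waveletName = "db1",
           nLevels = 1L, nOrig = 2L)
  eRaw <- subbandEnergies(d, waveletParams("db1", 1L, energyMode = "raw_sum"))
  eMean <- subbandEnergies(d, waveletParams("db1", 1L))
  expect_equal(unname(subbandEnergy(eRaw)[1, "D1"]), 9)
  expect_equal(unname(subbandEnergy(eMean)[1, "D1"]), 9)

  ## all-zero coefficients: zero energies and zero total
  x0 <- dwtDecompose(rep(0, 64), waveletParams(nLevels = 3L))
  e0 <- subbandEnergies(x0)
  expect_true(all(subbandEnergy(e0) == 0))
  expect_equal(e0@eTotal, 0)

  ## raw-sum energies add up to the signal energy (Parseval partition)
  set.seed(1)
  x <- rnorm(256)
  eR <- subbandEnergies(dwtDecompose(x, waveletParams(nLevels = 4L)),
                        waveletParams(nLevels = 4L, energyMode = "raw_sum"))
  expect_equal(sum(subbandEnergy(eR)), sum(x^2), tolerance = 1e-10)
})

test_that("white-noise subband energies are flat in mean-per-coefficient mode", {
  set.seed(77)
  p <- waveletParams(nLevels = 4L)
  acc <- matrix(0, 200, 5)
  for (r in 1:200) {
    e <- subbandEnergies(dwtDecompose(rnorm(256), p), p)
    acc[r, ] <- subbandEnergy(e)[1, ]
  }
  mu <- colMeans(acc)
  ## every band estimates the same per-coefficient variance (= 1)
  expect_true(all(abs(mu - 1) < 0.1))
})

test_that("relative energies normalise, are scale invariant, and error on zero", {
  mkE <- function(E, mode = "raw_sum") {
    new("EnergyDistribution", E = matrix(E, 1), nCoeffs = matrix(1, 1, length(E)),
        eTotal = sum(E), P = matrix(numeric(0), 0, 0), mode = mode)
  }
  e <- relativeEnergies(mkE(c(2, 1, 1)))
  expect_equal(relEnergy(e)[1, ], c(0.5, 0.25, 0.25))
  set.seed(2)
  for (r in 1:20) {
    E <- rexp(7)
    expect_equal(sum(relEnergy(relativeEnergies(mkE(E)))), 1, tolerance = 1e-12)
    expect_equal(relEnergy(relativeEnergies(mkE(E * runif(1, 0.1, 100)))),
                 relEnergy(relativeEnergies(mkE(E))), tolerance = 1e-12)
  }
  expect_error(relativeEnergies(mkE(c(0, 0, 0))), "zero total energy")
})

test_that("Shannon wavelet entropy matches direct evaluation and its bounds", {
  expect_equal(shannonWaveletEntropy(c(1, 0, 0, 0, 0, 0, 0)), 0)
  expect_equal(shannonWaveletEntropy(rep(1 / 7, 7)), log(7), tolerance = 1e-12)
  ## independent evaluation of -sum p ln p
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannonWaveletEntropy(p), -sum(p * log(p)))
  expect_equal(shannonWaveletEntropy(p), 1.0397, tolerance = 1e-4)
  expect_error(shannonWaveletEntropy(c(0.9, 0.2)), "sum")
  expect_error(shannonWaveletEntropy(c(1.2, -0.2)), "nonnegative")

  ## bounds over random distributions; ceiling only for the uniform one
  set.seed(9)
  for (r in 1:50) {
    p <- rexp(7); p <- p / sum(p)
    h <- shannonWaveletEntropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(7) + 1e-12)
    if (max(abs(p - 1 / 7)) > 0.05) expect_lt(h, log(7))
  }
})

test_that("entropy separates narrow-band signals from broadband noise", {
  set.seed(30)
  p <- waveletParams(nLevels = 6L)
  entOf <- function(x)
    shannonWaveletEntropy(relativeEnergies(subbandEnergies(dwtDecompose(x, p), p)))
  tt <- (0:2047) / 64
  hSine <- entOf(sin(2 * pi * 0.25 * tt))
  hNoise <- entOf(rnorm(2048))
  expect_lt(hSine, 0.35 * log(7))
  expect_gt(hNoise, 0.9 * log(7))
  ## amplitude invariance of the statistic
  expect_equal(entOf(500 * sin(2 * pi * 0.25 * tt)), hSine, tolerance = 1e-9)
})

test_that("raw-sum white-noise relative energies follow the halving bandwidths", {
  ## P_j ~ 2^-j (detail j), approximation ~ 2^-J: H -> 2 ln 2 for large J
  set.seed(55)
  J <- 8L
  p <- waveletParams(nLevels = J, energyMode = "raw_sum")
  hs <- replicate(30, {
    e <- relativeEnergies(subbandEnergies(dwtDecompose(rnorm(4096), p), p))
    shannonWaveletEntropy(e)
  })
  closedForm <- sum(2^-(1:J) * (1:J) * log(2)) + 2^-J * J * log(2)
  expect_equal(mean(hs), closedForm, tolerance = 0.03)
  expect_equal(closedForm, 2 * log(2), tolerance = 0.02)
})

test_that("windowed entropy averages across non-overlapping windows", {
  set.seed(14)
  x <- rnorm(1024)
  pFull <- waveletParams(nLevels = 3L)
  pWin <- waveletParams(nLevels = 3L, windowLen = 256L)
  d <- dwtDecompose(x, pWin)
  e <- subbandEnergies(d, pWin)
  expect_identical(dim(subbandEnergy(e)), c(4L, 4L))
  hw <- shannonWaveletEntropy(relativeEnergies(e))
  expect_length(hw, 4L)
  ## each window's energies equal those of the corresponding coefficient chunk
  cf <- waveletCoeffs(d)
  manual <- mean(sapply(1:4, function(i) {
    E <- vapply(seq_along(cf), function(j) {
      nj <- length(cf[[j]]) / 4
      chunk <- cf[[j]][((i - 1) * nj + 1):(i * nj)]
      sum(chunk^2) / nj
    }, 0)
    -sum((E / sum(E)) * log(E / sum(E)))
  }))
  expect_equal(mean(hw), manual, tolerance = 1e-10)
  expect_error(subbandEnergies(d, waveletParams(nLevels = 3L, windowLen = 100L)),
               "divide")
})

test_that("the entropy spectrum flags zero-energy bins at the ceiling", {
  set.seed(6)
  data <- rbind(rnorm(512), 0, rnorm(512))
  m <- echoMatrix(data, fastDtNs = 1, slowFsHz = 64)
  expect_message(es <- entropySpectrum(m, waveletParams(nLevels = 4L)),
                 "zero-energy")
  expect_equal(entropyValues(es)[2], log(5))
  expect_true(es@zeroEnergy[2])
  expect_false(any(es@zeroEnergy[c(1, 3)]))
})

test_that("the entropy spectrum is deterministic given the same input", {
  cfg <- smallScene(targets = list(targetSpec(3)), seed = 10L)
  p <- waveletParams(nLevels = 5L)
  m <- autocorrelateMatrix(preprocessEcho(simulateScene(cfg),
                                          preprocessParams(nRangeBins = 50L)))
  expect_identical(entropyValues(entropySpectrum(m, p)),
                   entropyValues(entropySpectrum(m, p)))
})
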