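test_that("fast-time delay maps to range by r = c tau / 2", {
  expect_equal(fastTimeToRange(60), 9.0)
  expect_equal(fastTimeToRange(0), 0.0)
  expect_equal(fastTimeToRange(20), 3.0)
  expect_error(fastTimeToRange(-1), "nonnegative")
})

test_that("distance accumulation partitions rows and conserves the sum", {
  m <- echoMatrix(matrix(1, 2048, 4), fastDtNs = 60 / 2048, slowFsHz = 64)
  acc <- rangeAccumulate(m, 200)
  expect_identical(dim(acc), c(200L, 4L))

  ## brute-force block-partition oracle: same grouping rule, naive loop
  grp <- floor((seq_len(2048) - 1) * 200 / 2048) + 1
  sizes <- as.integer(table(grp))
  expect_true(all(sizes %in% c(10L, 11L)))
  expect_identical(sum(sizes == 10L), 152L)
  expect_identical(sum(sizes == 11L), 48L)
  ## all-ones input: each output entry equals its block size
  expect_equal(echoData(acc)[, 1], as.numeric(sizes))
  expect_equal(colSums(echoData(acc)), rep(2048, 4))

  ## sum conservation on arbitrary data
  set.seed(5)
  m2 <- echoMatrix(matrix(rnorm(512 * 16), 512, 16), fastDtNs = 60 / 512,
                   slowFsHz = 64)
  expect_equal(sum(echoData(rangeAccumulate(m2, 50))), sum(echoData(m2)),
               tolerance = 1e-12)

  ## zero in, zero out; too many bins errors
  mz <- echoMatrix(matrix(0, 64, 8), fastDtNs = 1, slowFsHz = 64)
  expect_true(all(echoData(rangeAccumulate(mz, 16)) == 0))
  expect_error(rangeAccumulate(mz, 65), "cannot accumulate")
})

test_that("clutter removal kills constants, is linear, matches its frequency response", {
  fs <- 64
  n <- 2048
  mkRow <- function(x) echoMatrix(matrix(x, 1, n), fastDtNs = 1, slowFsHz = fs)
  ## constant row -> exactly zero
  out <- echoData(removeStaticClutter(mkRow(rep(5, n)), 100))
  expect_equal(max(abs(out)), 0)

  ## closed-form moving-average response at 0.25 Hz: subtraction leaves
  ## |1 - D| of the amplitude (D = Dirichlet gain of the 101-sample window)
  tt <- (0:(n - 1)) / fs
  s <- sin(2 * pi * 0.25 * tt)
  outS <- echoData(removeStaticClutter(mkRow(s), 100))[1, ]
  D <- movingAvgGain(0.25, fs, 100)
  core <- 200:(n - 200)          # away from edge-truncated windows
  ratio <- sqrt(sum(outS[core]^2) / sum(s[core]^2))
  expect_equal(ratio, abs(1 - D), tolerance = 0.02)

  ## constant + sinusoid -> same as filtered sinusoid alone (linearity)
  outCS <- echoData(removeStaticClutter(mkRow(3 + s), 100))[1, ]
  expect_equal(outCS, outS, tolerance = 1e-10)

  ## linear drift is removed exactly away from the edges, so interior
  ## moving-window means of the output vanish
  drift <- seq(0, 1, length.out = n)
  outD <- echoData(removeStaticClutter(mkRow(2 + 3 * drift), 100))[1, ]
  expect_lt(max(abs(outD[100:(n - 100)])), 1e-9)

  short <- echoMatrix(matrix(1, 1, 50), fastDtNs = 1, slowFsHz = fs)
  expect_error(removeStaticClutter(short, 100), "shorter")
})

test_that("FIR low-pass preserves the passband and rejects the stopband", {
  fs <- 64
  n <- 1024
  tt <- (0:(n - 1)) / fs
  mkRow <- function(x) echoMatrix(matrix(x, 1, n), fastDtNs = 1, slowFsHz = fs)
  core <- 200:(n - 200)

  ## DC passes within 1%
  dc <- echoData(lowpassSlowTime(mkRow(rep(1, n)), 4, 64))[1, ]
  expect_lt(max(abs(dc[core] - 1)), 0.01)

  ## 0.25 Hz tone amplitude preserved within 5%
  tone <- sin(2 * pi * 0.25 * tt)
  y <- echoData(lowpassSlowTime(mkRow(tone), 4, 64))[1, ]
  expect_equal(sqrt(mean(y[core]^2)) / sqrt(mean(tone[core]^2)), 1,
               tolerance = 0.05)
  ## group delay compensated: output in phase with input
  expect_gt(cor(y[core], tone[core]), 0.999)

  ## 16 Hz tone with 4 Hz cutoff: at least 20 dB down
  hiTone <- sin(2 * pi * 16 * tt)
  yh <- echoData(lowpassSlowTime(mkRow(hiTone), 4, 64))[1, ]
  expect_lt(sqrt(mean(yh[core]^2)) / sqrt(mean(hiTone[core]^2)), 0.1)

  expect_error(lowpassSlowTime(mkRow(tone), 40, 64), "Nyquist")
  expect_error(lowpassSlowTime(mkRow(tone), 4, 1), "order")
})

test_that("the preprocessing chain is linear and shape-correct", {
  set.seed(21)
  mk <- function(d) echoMatrix(d, fastDtNs = 60 / 512, slowFsHz = 64)
  X <- matrix(rnorm(512 * 256), 512, 256)
  Y <- matrix(rnorm(512 * 256), 512, 256)
  p <- preprocessParams(nRangeBins = 50L)
  chain <- function(d) echoData(preprocessEcho(mk(d), p))
  lhs <- chain(2 * X - 3 * Y)
  rhs <- 2 * chain(X) - 3 * chain(Y)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_identical(dim(lhs), c(50L, 256L))
})
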