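## Shared fixtures, all generated in code.

## Small fast scene: 512 fast-time rows, 8 s record (512 pulses).
smallScene <- function(targets = list(), seed = 1L, ...) {
  sceneConfig(targets = targets, nFast = 512L, durationS = 8, seed = seed, ...)
}

## Full-size study scene: 2048 x 2048, two targets at radar constants.
studyScene <- function(rangeB = 6, angleB = 0, seed = 1L, ...) {
  sceneConfig(targets = list(targetSpec(3, respFreqHz = 0.3),
                             targetSpec(rangeB, angleDeg = angleB,
                                        respFreqHz = 0.25)),
              seed = seed, ...)
}

## Frequency of the discrete-spectrum maximum of a vector (one-sided).
fftPeakHz <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  (which.max(sp) - 1L) * fs / n
}

## Closed-form gain of a centred (2k+1)-sample moving average at f/fs.
movingAvgGain <- function(fHz, fsHz, winLen) {
  w <- 2L * (winLen %/% 2L) + 1L   # effective odd width
  sin(pi * fHz * w / fsHz) / (w * sin(pi * fHz / fsHz))
}

## Hand-rolled entropy spectrum from a constructed H vector.
spectrumFromH <- function(H, binW = 0.045, params = list()) {
  new("EntropySpectrum", H = H, rangeAxisM = seq_along(H) * binW,
      zeroEnergy = logical(length(H)), params = params)
}
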