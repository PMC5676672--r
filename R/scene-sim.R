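## Synthetic scene generator: builds fast-time x slow-time echo matrices
## with the statistical structure the detection pipeline assumes — static
## wall clutter, quasi-sinusoidal respiration signatures spread over the
## torso footprint, 1/r^2 propagation loss, a hard shadow cone behind the
## nearest target, trailing multipath, and white Gaussian receiver noise.

## Range footprint of a target: raised-cosine (Hann) envelope of compact
## support body thickness + pulse extent c/(2B). Same half-power width as
## a Gaussian of that -3 dB width, but a finite footprint, so the entropy
## pit of even a very strong target cannot outgrow the torso gate.
.targetEnvelope <- function(rangeAxisM, centerM, bodyThicknessM) {
  pulseM <- .C_LIGHT / (2 * .PULSE_BANDWIDTH_HZ)   # 0.3 m at 500 MHz
  w <- bodyThicknessM + pulseM
  d <- rangeAxisM - centerM
  env <- numeric(length(d))
  inside <- abs(d) < w / 2
  env[inside] <- cos(pi * d[inside] / w)^2
  env
}

#' Shadow attenuation between two targets
#'
#' A nearer body reflects part of the illumination, casting a hard conical
#' shadow behind itself. A target farther than \code{front} whose bearing
#' lies within the cone half-angle of \code{front}'s bearing has its echo
#' amplitude multiplied by \code{shadowAtten}; boundary bearings (angular
#' separation equal to the half-angle) count as inside the cone. A target
#' nearer than \code{front} is never shadowed and the factor is 1.
#'
#' @param front the \linkS4class{TargetSpec} casting the shadow.
#' @param back the \linkS4class{TargetSpec} possibly inside the cone.
#' @param config a \linkS4class{SceneConfig} supplying
#'   \code{shadowHalfAngleDeg} and \code{shadowAtten}.
#' @return The amplitude factor, \code{shadowAtten} or 1.
#' @examples
#' cfg <- sceneConfig()
#' shadowFactor(targetSpec(3, angleDeg = 0), targetSpec(6, angleDeg = 10), cfg)
#' @export
shadowFactor <- function(front, back, config) {
  if (back@rangeM <= front@rangeM) return(1.0)
  sep <- abs(back@angleDeg - front@angleDeg)
  if (sep <= config@shadowHalfAngleDeg) config@shadowAtten else 1.0
}

#' Simulate a radar scene
#'
#' Builds an M x N echo matrix as the sum of: (a) a static wall-clutter
#' profile, constant along slow time, inside the wall band; (b) for each
#' target, its torso-footprint envelope modulated sinusoidally at the
#' respiration frequency along slow time, scaled by 1/r^2 propagation loss
#' and by the shadow factor of any nearer target whose cone covers it;
#' (c) a trailing multipath replica of each target's modulation behind its
#' torso; and (d) independent zero-mean Gaussian noise. The result is
#' bit-reproducible given \code{config@seed}.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return An \linkS4class{EchoMatrix} of
#'   \code{nFast} x \code{slowFsHz * durationS} samples.
#' @examples
#' m <- simulateScene(sceneConfig(targets = list(targetSpec(3)),
#'                                nFast = 512L, durationS = 4))
#' dim(m)
#' @export
simulateScene <- function(config) {
  validObject(config)
  r <- vapply(config@targets, function(t) t@rangeM, 0)
  if (anyDuplicated(r))
    configError("two targets share the same range; overlapping targets are not supported")

  M <- config@nFast
  N <- as.integer(round(config@slowFsHz * config@durationS))
  dt <- config@fastWindowNs / M
  rangeAxis <- fastTimeToRange(seq_len(M) * dt)
  tt <- (seq_len(N) - 1) / config@slowFsHz

  data <- matrix(0, nrow = M, ncol = N)

  ## deterministic (seed-independent) target and trail components
  for (tg in config@targets) {
    shade <- 1.0
    for (other in config@targets)
      if (!identical(other, tg))
        shade <- min(shade, shadowFactor(other, tg, config))
    amp <- tg@respAmp / tg@rangeM^2 * shade
    resp <- sin(2 * pi * tg@respFreqHz * tt + tg@phaseRad)
    env <- .targetEnvelope(rangeAxis, tg@rangeM, tg@bodyThicknessM)
    if (any(env > 0))
      data <- data + amp * tcrossprod(env, resp)
    if (config@trailAmpFrac > 0 && config@trailLengthM > 0) {
      pulseM <- .C_LIGHT / (2 * .PULSE_BANDWIDTH_HZ)
      rear <- tg@rangeM + (tg@bodyThicknessM + pulseM) / 2
      lo <- rear + config@trailGapM
      hi <- lo + config@trailLengthM
      trail <- as.numeric(rangeAxis >= lo & rangeAxis <= hi)
      if (any(trail > 0)) {
        ## longer bounce path: same frequency, shifted phase
        respTrail <- sin(2 * pi * tg@respFreqHz * tt + tg@phaseRad + pi / 3)
        data <- data + (config@trailAmpFrac * amp) * tcrossprod(trail, respTrail)
      }
    }
  }

  ## seeded components: static wall profile, then receiver noise
  withSeed(config@seed, {
    if (config@wallAmp > 0) {
      wall <- which(rangeAxis >= config@wallRangeM[1] &
                    rangeAxis <= config@wallRangeM[2])
      if (length(wall))
        data[wall, ] <- data[wall, ] + config@wallAmp * rnorm(length(wall))
    }
    if (config@noiseSigma > 0)
      data <- data + matrix(rnorm(M * N, sd = config@noiseSigma), M, N)
  })

  echoMatrix(data, fastDtNs = dt, slowFsHz = config@slowFsHz,
             rangeAxisM = rangeAxis, axisType = "slow_time")
}
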