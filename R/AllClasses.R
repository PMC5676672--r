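#' @import methods
NULL

## Speed of light used for the two-way delay <-> range conversion, m/s.
.C_LIGHT <- 3e8

## Nominal -3 dB pulse bandwidth of the radar front end, Hz. Sets the
## range resolution c/(2B) = 0.3 m that widens every target footprint.
.PULSE_BANDWIDTH_HZ <- 500e6

#' TargetSpec: one stationary breathing human in a simulated scene
#'
#' Describes a single target by its radial range from the antennas, its
#' bearing relative to boresight, and its respiration signature. The torso
#' is modelled as a reflecting slab of finite thickness, so the echo is
#' spread over several neighbouring fast-time cells; the chest motion
#' amplitude-modulates the echo sinusoidally along slow time.
#'
#' @slot rangeM radial distance from the antennas, metres, in (0, 9].
#' @slot angleDeg bearing relative to boresight, degrees.
#' @slot respFreqHz respiration frequency, Hz (cycles per second).
#' @slot respAmp dimensionless echo modulation amplitude at 1 m range
#'   (before 1/r^2 propagation loss), >= 0.
#' @slot bodyThicknessM spatial extent of the reflecting torso, metres, > 0.
#' @slot phaseRad initial phase of the respiration cycle, radians.
#'
#' @exportClass TargetSpec
setClass("TargetSpec",
  representation(
    rangeM = "numeric",
    angleDeg = "numeric",
    respFreqHz = "numeric",
    respAmp = "numeric",
    bodyThicknessM = "numeric",
    phaseRad = "numeric"
  )
)

setValidity("TargetSpec", function(object) {
  msg <- character()
  if (length(object@rangeM) != 1L || !is.finite(object@rangeM) ||
      object@rangeM <= 0 || object@rangeM > 9)
    msg <- c(msg, "rangeM must be a single value in (0, 9]")
  if (length(object@respFreqHz) != 1L || object@respFreqHz <= 0)
    msg <- c(msg, "respFreqHz must be positive")
  if (length(object@respAmp) != 1L || object@respAmp < 0)
    msg <- c(msg, "respAmp must be >= 0")
  if (length(object@bodyThicknessM) != 1L || object@bodyThicknessM <= 0)
    msg <- c(msg, "bodyThicknessM must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TargetSpec
#'
#' @param rangeM radial range from the antennas, metres.
#' @param angleDeg bearing relative to boresight, degrees.
#' @param respFreqHz respiration frequency, Hz.
#' @param respAmp echo modulation amplitude at 1 m (before propagation loss).
#' @param bodyThicknessM torso thickness, metres.
#' @param phaseRad initial respiration phase, radians.
#' @return A \linkS4class{TargetSpec}.
#' @examples
#' targetSpec(rangeM = 3, respFreqHz = 0.3)
#' @export
targetSpec <- function(rangeM, angleDeg = 0, respFreqHz = 0.25,
                       respAmp = 1, bodyThicknessM = 0.4, phaseRad = 0) {
  new("TargetSpec", rangeM = as.numeric(rangeM), angleDeg = as.numeric(angleDeg),
      respFreqHz = as.numeric(respFreqHz), respAmp = as.numeric(respAmp),
      bodyThicknessM = as.numeric(bodyThicknessM), phaseRad = as.numeric(phaseRad))
}

#' SceneConfig: geometry and noise model of a simulated radar scene
#'
#' Collects everything the simulator needs: scene geometry (targets and
#' wall), radar timing constants (fast-time window, slow-time rate), the
#' shadowing-cone model, trailing multipath, and receiver noise.
#'
#' The shadow model is a hard cone: a target sitting farther than another
#' target and within \code{shadowHalfAngleDeg} of its bearing has its echo
#' amplitude multiplied by \code{shadowAtten}. Trailing multipath (ground
#' bounce) re-radiates each target's respiration modulation over
#' \code{trailLengthM} behind the torso, starting \code{trailGapM} behind
#' its rear face, at \code{trailAmpFrac} of the target amplitude.
#'
#' @slot targets list of \linkS4class{TargetSpec}.
#' @slot nFast fast-time samples per waveform (rows of the echo matrix).
#' @slot fastWindowNs recorded fast-time duration, nanoseconds.
#' @slot slowFsHz slow-time (pulse-to-pulse) sampling rate, Hz.
#' @slot durationS slow-time record length, seconds.
#' @slot wallRangeM two-element range band occupied by the wall, metres.
#' @slot wallAmp static wall-clutter amplitude.
#' @slot noiseSigma standard deviation of additive Gaussian receiver noise.
#' @slot shadowHalfAngleDeg half-angle of the shadow cone, degrees.
#' @slot shadowAtten amplitude factor inside a shadow cone, in (0, 1].
#' @slot trailLengthM extent of trailing multipath behind a target, metres.
#' @slot trailAmpFrac trailing amplitude as a fraction of target amplitude.
#' @slot trailGapM gap between the torso rear face and the trail onset, metres.
#' @slot seed integer RNG seed; the simulation is deterministic given it.
#'
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    targets = "list",
    nFast = "integer",
    fastWindowNs = "numeric",
    slowFsHz = "numeric",
    durationS = "numeric",
    wallRangeM = "numeric",
    wallAmp = "numeric",
    noiseSigma = "numeric",
    shadowHalfAngleDeg = "numeric",
    shadowAtten = "numeric",
    trailLengthM = "numeric",
    trailAmpFrac = "numeric",
    trailGapM = "numeric",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@targets, is, logical(1), "TargetSpec")))
    msg <- c(msg, "targets must all be TargetSpec objects")
  if (object@nFast <= 0L) msg <- c(msg, "nFast must be > 0")
  if (object@slowFsHz <= 0) msg <- c(msg, "slowFsHz must be > 0")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (length(object@wallRangeM) != 2L || diff(object@wallRangeM) < 0)
    msg <- c(msg, "wallRangeM must be an increasing length-2 band")
  if (object@shadowAtten <= 0 || object@shadowAtten > 1)
    msg <- c(msg, "shadowAtten must be in (0, 1]")
  if (object@trailLengthM < 0) msg <- c(msg, "trailLengthM must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  nyq <- object@slowFsHz / 2
  for (tg in object@targets)
    if (tg@respFreqHz >= nyq)
      msg <- c(msg, "target respFreqHz must be below the slow-time Nyquist rate")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneConfig
#'
#' Defaults reproduce the radar constants of the bistatic IR-UWB system the
#' pipeline was designed around: 2048 fast-time points over a 60 ns window
#' (9 m unambiguous range), 64 slow-time samples per second, and a 32 s
#' record (2048 pulses, a power of two convenient for a full dyadic DWT).
#'
#' @param targets list of \linkS4class{TargetSpec} objects.
#' @param nFast fast-time samples (default 2048).
#' @param fastWindowNs fast-time window, ns (default 60).
#' @param slowFsHz slow-time rate, Hz (default 64).
#' @param durationS record length, s (default 32).
#' @param wallRangeM wall-clutter band, metres (default c(0, 1)).
#' @param wallAmp wall-clutter amplitude (default 5).
#' @param noiseSigma receiver-noise standard deviation (default 0.005).
#' @param shadowHalfAngleDeg shadow-cone half angle, degrees (default 20).
#' @param shadowAtten amplitude factor inside the cone (default 0.1).
#' @param trailLengthM trailing-multipath extent, metres (default 1).
#' @param trailAmpFrac trailing amplitude fraction (default 0, no trailing).
#' @param trailGapM gap before trail onset, metres (default 0.15).
#' @param seed integer RNG seed (default 1).
#' @return A \linkS4class{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(targets = list(targetSpec(3), targetSpec(6)))
#' @export
sceneConfig <- function(targets = list(), nFast = 2048L, fastWindowNs = 60,
                        slowFsHz = 64, durationS = 32, wallRangeM = c(0, 1),
                        wallAmp = 5, noiseSigma = 0.005,
                        shadowHalfAngleDeg = 20, shadowAtten = 0.1,
                        trailLengthM = 1.0, trailAmpFrac = 0,
                        trailGapM = 0.15, seed = 1L) {
  new("SceneConfig", targets = targets, nFast = as.integer(nFast),
      fastWindowNs = as.numeric(fastWindowNs), slowFsHz = as.numeric(slowFsHz),
      durationS = as.numeric(durationS), wallRangeM = as.numeric(wallRangeM),
      wallAmp = as.numeric(wallAmp), noiseSigma = as.numeric(noiseSigma),
      shadowHalfAngleDeg = as.numeric(shadowHalfAngleDeg),
      shadowAtten = as.numeric(shadowAtten),
      trailLengthM = as.numeric(trailLengthM),
      trailAmpFrac = as.numeric(trailAmpFrac),
      trailGapM = as.numeric(trailGapM), seed = as.integer(seed))
}

#' EchoMatrix: a fast-time by slow-time radar sample grid
#'
#' The central data container. Rows index fast time (equivalently range,
#' via r = c tau / 2 with tau the two-way delay); columns index slow time
#' (successive pulses) or, after auto-correlation, lag. Row/axis metadata
#' travel with the samples through every stage of the pipeline.
#'
#' @slot data numeric matrix, fast-time rows by slow-time (or lag) columns.
#' @slot fastDtNs fast-time step between rows, nanoseconds.
#' @slot slowFsHz slow-time sampling rate, Hz.
#' @slot rangeAxisM per-row range, metres, strictly increasing.
#' @slot axisType column-axis label, \code{"slow_time"} or \code{"lag"}.
#'
#' @exportClass EchoMatrix
setClass("EchoMatrix",
  representation(
    data = "matrix",
    fastDtNs = "numeric",
    slowFsHz = "numeric",
    rangeAxisM = "numeric",
    axisType = "character"
  )
)

setValidity("EchoMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (nrow(object@data) != length(object@rangeAxisM))
    msg <- c(msg, "rangeAxisM length must equal nrow(data)")
  if (length(object@rangeAxisM) > 1L && any(diff(object@rangeAxisM) <= 0))
    msg <- c(msg, "rangeAxisM must be strictly increasing")
  if (!object@axisType %in% c("slow_time", "lag"))
    msg <- c(msg, "axisType must be 'slow_time' or 'lag'")
  if (object@slowFsHz <= 0) msg <- c(msg, "slowFsHz must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an EchoMatrix
#'
#' @param data numeric matrix (fast-time rows, slow-time columns).
#' @param fastDtNs fast-time step, ns.
#' @param slowFsHz slow-time rate, Hz.
#' @param rangeAxisM per-row ranges, metres. If \code{NULL}, computed from
#'   \code{fastDtNs} as r_m = c (m dt) / 2 for rows m = 1..M.
#' @param axisType \code{"slow_time"} (default) or \code{"lag"}.
#' @return An \linkS4class{EchoMatrix}.
#' @export
echoMatrix <- function(data, fastDtNs, slowFsHz, rangeAxisM = NULL,
                       axisType = "slow_time") {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (is.null(rangeAxisM))
    rangeAxisM <- fastTimeToRange(seq_len(nrow(data)) * fastDtNs)
  new("EchoMatrix", data = data, fastDtNs = as.numeric(fastDtNs),
      slowFsHz = as.numeric(slowFsHz), rangeAxisM = as.numeric(rangeAxisM),
      axisType = axisType)
}

#' PreprocessParams: settings for the three-stage preprocessing chain
#'
#' @slot nRangeBins number of output range bins after distance accumulation.
#' @slot clutterWindow sliding-window width for clutter subtraction,
#'   slow-time samples.
#' @slot lpCutoffHz FIR low-pass cutoff, Hz.
#' @slot lpOrder FIR filter order (taps = order + 1).
#'
#' @exportClass PreprocessParams
setClass("PreprocessParams",
  representation(nRangeBins = "integer", clutterWindow = "integer",
                 lpCutoffHz = "numeric", lpOrder = "integer")
)

setValidity("PreprocessParams", function(object) {
  msg <- character()
  if (object@nRangeBins < 1L) msg <- c(msg, "nRangeBins must be >= 1")
  if (object@clutterWindow < 2L) msg <- c(msg, "clutterWindow must be >= 2")
  if (object@lpCutoffHz <= 0) msg <- c(msg, "lpCutoffHz must be > 0")
  if (object@lpOrder < 2L) msg <- c(msg, "lpOrder must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct PreprocessParams
#'
#' @param nRangeBins output range-bin count (default 200).
#' @param clutterWindow clutter sliding-window width, samples (default 100).
#' @param lpCutoffHz FIR low-pass cutoff, Hz (default 16).
#' @param lpOrder FIR order (default 64).
#' @return A \linkS4class{PreprocessParams}.
#' @export
preprocessParams <- function(nRangeBins = 200L, clutterWindow = 100L,
                             lpCutoffHz = 16.0, lpOrder = 64L) {
  new("PreprocessParams", nRangeBins = as.integer(nRangeBins),
      clutterWindow = as.integer(clutterWindow),
      lpCutoffHz = as.numeric(lpCutoffHz), lpOrder = as.integer(lpOrder))
}

#' AutocorrParams: auto-correlation estimator settings
#'
#' @slot estimator \code{"biased"} (divide by N; guarantees |R(k)| <= R(0)
#'   and a nonnegative spectrum) or \code{"unbiased"} (divide by N - k).
#' @slot maxLag number of positive lags retained; \code{NA} means N - 1.
#' @slot normalize divide by the zero-lag value.
#'
#' @exportClass AutocorrParams
setClass("AutocorrParams",
  representation(estimator = "character", maxLag = "integer",
                 normalize = "logical")
)

setValidity("AutocorrParams", function(object) {
  if (!object@estimator %in% c("biased", "unbiased"))
    "estimator must be 'biased' or 'unbiased'" else TRUE
})

#' Construct AutocorrParams
#'
#' @param estimator \code{"biased"} (default) or \code{"unbiased"}.
#' @param maxLag lags retained (default \code{NA}: N - 1).
#' @param normalize divide by R(0) (default \code{FALSE}).
#' @return An \linkS4class{AutocorrParams}.
#' @export
autocorrParams <- function(estimator = "biased", maxLag = NA_integer_,
                           normalize = FALSE) {
  new("AutocorrParams", estimator = estimator, maxLag = as.integer(maxLag),
      normalize = normalize)
}

#' WaveletParams: DWT and wavelet-entropy settings
#'
#' @slot waveletName orthogonal Daubechies family member, \code{"db1"},
#'   \code{"db2"}, \code{"db4"}, \code{"db6"} or \code{"db8"} (the number is
#'   the vanishing-moment count; taps = 2x that).
#' @slot nLevels dyadic decomposition depth J; J detail subbands plus the
#'   level-J approximation are retained, J + 1 bands in total.
#' @slot windowLen temporal window length L in input samples; \code{NA}
#'   means a single window spanning the whole record.
#' @slot energyMode \code{"mean_per_coeff"} (energy divided by the
#'   coefficient count of the band in the window, which equalises
#'   white-noise bands) or \code{"raw_sum"}.
#' @slot windowCombine \code{"mean"} or \code{"max"} across windows.
#'
#' @exportClass WaveletParams
setClass("WaveletParams",
  representation(waveletName = "character", nLevels = "integer",
                 windowLen = "integer", energyMode = "character",
                 windowCombine = "character")
)

setValidity("WaveletParams", function(object) {
  msg <- character()
  if (!object@energyMode %in% c("mean_per_coeff", "raw_sum"))
    msg <- c(msg, "energyMode must be 'mean_per_coeff' or 'raw_sum'")
  if (!object@windowCombine %in% c("mean", "max"))
    msg <- c(msg, "windowCombine must be 'mean' or 'max'")
  if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct WaveletParams
#'
#' @param waveletName Daubechies member (default \code{"db4"}).
#' @param nLevels decomposition depth J (default 6, i.e. 7 subbands and an
#'   entropy ceiling of ln 7).
#' @param windowLen window length L in samples (default \code{NA}: one
#'   window over the whole record).
#' @param energyMode \code{"mean_per_coeff"} (default) or \code{"raw_sum"}.
#' @param windowCombine \code{"mean"} (default) or \code{"max"}.
#' @return A \linkS4class{WaveletParams}.
#' @export
waveletParams <- function(waveletName = "db4", nLevels = 6L,
                          windowLen = NA_integer_,
                          energyMode = "mean_per_coeff",
                          windowCombine = "mean") {
  new("WaveletParams", waveletName = waveletName, nLevels = as.integer(nLevels),
      windowLen = as.integer(windowLen), energyMode = energyMode,
      windowCombine = windowCombine)
}

#' WaveletDecomposition: dyadic DWT coefficients of one vector
#'
#' Holds the detail subbands D1..DJ (finest to coarsest) and the level-J
#' approximation AJ produced by the iterated two-channel filter bank.
#'
#' @slot coeffs named list of numeric coefficient vectors
#'   (\code{D1..DJ, AJ}).
#' @slot waveletName mother wavelet used.
#' @slot nLevels depth J.
#' @slot nOrig input signal length.
#'
#' @exportClass WaveletDecomposition
setClass("WaveletDecomposition",
  representation(coeffs = "list", waveletName = "character",
                 nLevels = "integer", nOrig = "integer")
)

setValidity("WaveletDecomposition", function(object) {
  if (length(object@coeffs) != object@nLevels + 1L)
    "coeffs must hold nLevels detail subbands plus one approximation" else TRUE
})

#' EnergyDistribution: windowed subband energies and relative energies
#'
#' @slot E windows-by-subbands energy matrix (columns D1..DJ, AJ).
#' @slot nCoeffs coefficient counts per window and subband.
#' @slot eTotal per-window total energy.
#' @slot P relative energies (rows sum to 1); empty until
#'   \code{\link{relativeEnergies}} is applied.
#' @slot mode energy mode used (\code{"mean_per_coeff"} or \code{"raw_sum"}).
#'
#' @exportClass EnergyDistribution
setClass("EnergyDistribution",
  representation(E = "matrix", nCoeffs = "matrix", eTotal = "numeric",
                 P = "matrix", mode = "character")
)

setValidity("EnergyDistribution", function(object) {
  msg <- character()
  if (any(object@E < 0)) msg <- c(msg, "energies must be nonnegative")
  if (nrow(object@P) > 0L) {
    s <- rowSums(object@P)
    ok <- object@eTotal > 0
    if (any(abs(s[ok] - 1) > 1e-9))
      msg <- c(msg, "relative energies must sum to 1 per window")
  }
  if (length(msg)) msg else TRUE
})

#' EntropySpectrum: wavelet entropy per range bin
#'
#' @slot H entropy H(tau) in nats, one value per range bin; bounded by
#'   ln(J + 1).
#' @slot rangeAxisM per-bin range, metres.
#' @slot zeroEnergy flags bins whose total subband energy was zero (their
#'   entropy is reported as the ceiling ln(J + 1): no structure means
#'   maximal disorder).
#' @slot params list of provenance (wavelet, levels, window, mode).
#'
#' @exportClass EntropySpectrum
setClass("EntropySpectrum",
  representation(H = "numeric", rangeAxisM = "numeric",
                 zeroEnergy = "logical", params = "list")
)

setValidity("EntropySpectrum", function(object) {
  if (length(object@H) != length(object@rangeAxisM))
    "H and rangeAxisM lengths must agree" else TRUE
})

#' DetectionParams: entropy-pit detection settings
#'
#' The detection threshold is relative: median(H) - k * MAD(H) over the
#' bins beyond the blind range, so adding a constant to the whole spectrum
#' leaves the detections unchanged. Pits are gated by physical width
#' (torso thickness); width-failing pits immediately behind an accepted
#' target are classified as trailing-multipath ghosts.
#'
#' @slot blindRangeM near-field exclusion (wall reflections), metres.
#' @slot pitK the k in median - k * MAD.
#' @slot minPitWidthM minimum accepted pit width, metres.
#' @slot maxPitWidthM maximum accepted pit width, metres.
#' @slot ghostWindowM region behind an accepted target scanned for ghosts,
#'   metres.
#'
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(blindRangeM = "numeric", pitK = "numeric",
                 minPitWidthM = "numeric", maxPitWidthM = "numeric",
                 ghostWindowM = "numeric")
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@minPitWidthM <= 0 || object@minPitWidthM >= object@maxPitWidthM)
    msg <- c(msg, "need 0 < minPitWidthM < maxPitWidthM")
  if (object@pitK <= 0) msg <- c(msg, "pitK must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct DetectionParams
#'
#' @param blindRangeM near-field exclusion, metres (default 1).
#' @param pitK robust-threshold multiplier k (default 3).
#' @param minPitWidthM minimum pit width, metres (default 0.2).
#' @param maxPitWidthM maximum pit width, metres (default 0.8).
#' @param ghostWindowM ghost scan region behind a target, metres (default 1).
#' @return A \linkS4class{DetectionParams}.
#' @export
detectionParams <- function(blindRangeM = 1.0, pitK = 3,
                            minPitWidthM = 0.2, maxPitWidthM = 0.8,
                            ghostWindowM = 1.0) {
  new("DetectionParams", blindRangeM = as.numeric(blindRangeM),
      pitK = as.numeric(pitK), minPitWidthM = as.numeric(minPitWidthM),
      maxPitWidthM = as.numeric(maxPitWidthM),
      ghostWindowM = as.numeric(ghostWindowM))
}

#' DetectionReport: classified entropy pits
#'
#' @slot detections data.frame with one row per candidate pit: range_m (pit
#'   minimum), lo_m / hi_m (pit interval edges), width_m, h_min, n_bins and
#'   status (\code{accepted}, \code{rejected_ghost}, \code{rejected_width}).
#' @slot threshold the robust entropy threshold used.
#' @slot params list of provenance.
#'
#' @exportClass DetectionReport
setClass("DetectionReport",
  representation(detections = "data.frame", threshold = "numeric",
                 params = "list")
)

#' RunConfig: a full pipeline configuration
#'
#' Binds the scene description and the per-stage parameter sets; validated
#' for cross-field consistency (filter cutoff below the slow-time Nyquist
#' rate, wavelet depth feasible for the record length).
#'
#' @slot scene \linkS4class{SceneConfig}.
#' @slot preprocess \linkS4class{PreprocessParams}.
#' @slot autocorr \linkS4class{AutocorrParams}.
#' @slot wavelet \linkS4class{WaveletParams}.
#' @slot detection \linkS4class{DetectionParams}.
#'
#' @exportClass RunConfig
setClass("RunConfig",
  representation(scene = "SceneConfig", preprocess = "PreprocessParams",
                 autocorr = "AutocorrParams", wavelet = "WaveletParams",
                 detection = "DetectionParams")
)

setValidity("RunConfig", function(object) {
  msg <- character()
  nyq <- object@scene@slowFsHz / 2
  if (object@preprocess@lpCutoffHz >= nyq)
    msg <- c(msg, sprintf("lpCutoffHz (%g) must be below the slow-time Nyquist rate (%g)",
                          object@preprocess@lpCutoffHz, nyq))
  n <- round(object@scene@slowFsHz * object@scene@durationS)
  if (2^object@wavelet@nLevels > n)
    msg <- c(msg, sprintf("wavelet depth %d infeasible for %d slow-time samples",
                          object@wavelet@nLevels, n))
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param scene a \linkS4class{SceneConfig}.
#' @param preprocess a \linkS4class{PreprocessParams}.
#' @param autocorr an \linkS4class{AutocorrParams}.
#' @param wavelet a \linkS4class{WaveletParams}.
#' @param detection a \linkS4class{DetectionParams}.
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(scene = sceneConfig(), preprocess = preprocessParams(),
                      autocorr = autocorrParams(), wavelet = waveletParams(),
                      detection = detectionParams()) {
  new("RunConfig", scene = scene, preprocess = preprocess,
      autocorr = autocorr, wavelet = wavelet, detection = detection)
}
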