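setMethod("show", "TargetSpec", function(object) {
  cat(sprintf(
    "TargetSpec: %.2f m at %.0f deg, %.2f Hz respiration (amp %.3g, torso %.2f m)\n",
    object@rangeM, object@angleDeg, object@respFreqHz, object@respAmp,
    object@bodyThicknessM))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d target(s), %d x %d samples (%g ns window, %g Hz slow rate, %g s)\n",
              length(object@targets), object@nFast,
              as.integer(round(object@slowFsHz * object@durationS)),
              object@fastWindowNs, object@slowFsHz, object@durationS))
  cat(sprintf("  noise sigma %g, wall amp %g in [%g, %g] m, shadow %g deg half-angle x%g\n",
              object@noiseSigma, object@wallAmp, object@wallRangeM[1],
              object@wallRangeM[2], object@shadowHalfAngleDeg,
              object@shadowAtten))
  for (t in object@targets) show(t)
})

setMethod("show", "EchoMatrix", function(object) {
  cat(sprintf("EchoMatrix: %d range rows x %d %s columns\n",
              nrow(object@data), ncol(object@data),
              sub("_", " ", object@axisType)))
  cat(sprintf("  range %.3f-%.3f m, slow rate %g Hz\n",
              min(object@rangeAxisM), max(object@rangeAxisM),
              object@slowFsHz))
})

setMethod("show", "WaveletDecomposition", function(object) {
  cat(sprintf("WaveletDecomposition: %s, %d levels on %d samples\n",
              object@waveletName, object@nLevels, object@nOrig))
  cat("  subband lengths:",
      paste(sprintf("%s=%d", names(object@coeffs), lengths(object@coeffs)),
            collapse = ", "), "\n")
})

setMethod("show", "EnergyDistribution", function(object) {
  cat(sprintf("EnergyDistribution (%s): %d window(s) x %d subbands%s\n",
              object@mode, nrow(object@E), ncol(object@E),
              if (nrow(object@P)) ", relative energies filled" else ""))
})

setMethod("show", "EntropySpectrum", function(object) {
  cat(sprintf("EntropySpectrum: %d bins over %.2f-%.2f m (%s, J=%d)\n",
              length(object@H), min(object@rangeAxisM),
              max(object@rangeAxisM), object@params$wavelet,
              object@params$nLevels))
  cat(sprintf("  H in [%.3f, %.3f] nats (ceiling ln(J+1) = %.3f)\n",
              min(object@H), max(object@H), log(object@params$nLevels + 1)))
})

setMethod("show", "DetectionReport", function(object) {
  d <- object@detections
  cat(sprintf("DetectionReport: %d accepted, %d ghost, %d width-rejected (threshold %.3f)\n",
              sum(d$status == "accepted"), sum(d$status == "rejected_ghost"),
              sum(d$status == "rejected_width"), object@threshold))
  if (nrow(d)) print(d, digits = 4)
})
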