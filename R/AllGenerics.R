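#' Extract the sample grid of an EchoMatrix
#'
#' @param object an \linkS4class{EchoMatrix}.
#' @return The numeric fast-time by slow-time matrix.
#' @export
setGeneric("echoData", function(object) standardGeneric("echoData"))

#' @describeIn echoData sample grid accessor
setMethod("echoData", "EchoMatrix", function(object) object@data)

#' Per-row range axis
#'
#' @param object an \linkS4class{EchoMatrix} or \linkS4class{EntropySpectrum}.
#' @return Numeric vector of ranges in metres, one per row/bin.
#' @export
setGeneric("rangeAxis", function(object) standardGeneric("rangeAxis"))

#' @describeIn rangeAxis range axis of an echo matrix
setMethod("rangeAxis", "EchoMatrix", function(object) object@rangeAxisM)

#' @describeIn rangeAxis range axis of an entropy spectrum
setMethod("rangeAxis", "EntropySpectrum", function(object) object@rangeAxisM)

#' Slow-time sampling rate
#'
#' @param object an \linkS4class{EchoMatrix}.
#' @return Sampling rate in Hz.
#' @export
setGeneric("slowRate", function(object) standardGeneric("slowRate"))

#' @describeIn slowRate slow-time rate accessor
setMethod("slowRate", "EchoMatrix", function(object) object@slowFsHz)

#' Column-axis type of an EchoMatrix
#'
#' @param object an \linkS4class{EchoMatrix}.
#' @return \code{"slow_time"} or \code{"lag"}.
#' @export
setGeneric("axisType", function(object) standardGeneric("axisType"))

#' @describeIn axisType axis-type accessor
setMethod("axisType", "EchoMatrix", function(object) object@axisType)

#' @describeIn echoData matrix dimensions
#' @export
setMethod("dim", "EchoMatrix", function(x) dim(x@data))

#' Wavelet-entropy values per range bin
#'
#' @param object an \linkS4class{EntropySpectrum}.
#' @return Numeric vector of entropies in nats.
#' @export
setGeneric("entropyValues", function(object) standardGeneric("entropyValues"))

#' @describeIn entropyValues entropy accessor
setMethod("entropyValues", "EntropySpectrum", function(object) object@H)

#' Candidate and accepted detections
#'
#' @param object a \linkS4class{DetectionReport}.
#' @param status optional status filter, e.g. \code{"accepted"}.
#' @return data.frame of pits (range_m, lo_m, hi_m, width_m, h_min, n_bins,
#'   status).
#' @export
setGeneric("detections", function(object, status = NULL)
  standardGeneric("detections"))

#' @describeIn detections detection-table accessor
setMethod("detections", "DetectionReport", function(object, status = NULL) {
  d <- object@detections
  if (!is.null(status)) d <- d[d$status %in% status, , drop = FALSE]
  d
})

#' Subband coefficients of a wavelet decomposition
#'
#' @param object a \linkS4class{WaveletDecomposition}.
#' @return Named list of coefficient vectors (D1..DJ, AJ).
#' @export
setGeneric("waveletCoeffs", function(object) standardGeneric("waveletCoeffs"))

#' @describeIn waveletCoeffs coefficient accessor
setMethod("waveletCoeffs", "WaveletDecomposition", function(object) object@coeffs)

#' Relative subband energies
#'
#' @param object an \linkS4class{EnergyDistribution}.
#' @return Windows-by-subbands matrix of relative energies (rows sum to 1).
#' @export
setGeneric("relEnergy", function(object) standardGeneric("relEnergy"))

#' @describeIn relEnergy relative-energy accessor
setMethod("relEnergy", "EnergyDistribution", function(object) object@P)

#' Subband energies
#'
#' @param object an \linkS4class{EnergyDistribution}.
#' @return Windows-by-subbands matrix of energies.
#' @export
setGeneric("subbandEnergy", function(object) standardGeneric("subbandEnergy"))

#' @describeIn subbandEnergy energy accessor
setMethod("subbandEnergy", "EnergyDistribution", function(object) object@E)
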