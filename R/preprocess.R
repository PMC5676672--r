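## Three-stage preprocessing: distance accumulation along fast time,
## sliding-window subtraction of static clutter along slow time, and a
## linear-phase FIR low-pass on each range bin's slow-time signal.

#' Two-way delay to range
#'
#' Converts a fast-time (two-way propagation) delay to range via
#' r = c * tau / 2.
#'
#' @param tauNs two-way delay(s), nanoseconds; must be nonnegative.
#' @return Range(s) in metres. A 60 ns delay maps to 9 m.
#' @examples
#' fastTimeToRange(60)  # 9
#' @export
fastTimeToRange <- function(tauNs) {
  if (any(tauNs < 0)) stop("two-way delay must be nonnegative", call. = FALSE)
  .C_LIGHT * (tauNs * 1e-9) / 2
}

#' Distance accumulation (fast-time compression)
#'
#' Partitions the fast-time rows into \code{nRangeBins} contiguous blocks
#' of near-equal size (sizes differ by at most one, evenly interleaved)
#' and sums each block into one output row. Summing rather than averaging
#' preserves the absolute energy of weak targets: the respiration
#' signature of one torso spans many native fast-time cells and adds
#' coherently within a block while noise adds only in quadrature. The
#' total sample sum of the matrix is conserved exactly; the output range
#' axis carries block-centre ranges.
#'
#' @param m an \linkS4class{EchoMatrix}.
#' @param nRangeBins output row count (default 200).
#' @return An \linkS4class{EchoMatrix} with \code{nRangeBins} rows.
#' @examples
#' m <- echoMatrix(matrix(1, 2048, 4), fastDtNs = 60 / 2048, slowFsHz = 64)
#' dim(rangeAccumulate(m, 200))
#' @export
rangeAccumulate <- function(m, nRangeBins = 200L) {
  M <- nrow(m@data)
  nRangeBins <- as.integer(nRangeBins)
  if (nRangeBins > M)
    stop(sprintf("cannot accumulate %d rows into %d bins", M, nRangeBins),
         call. = FALSE)
  grp <- floor((seq_len(M) - 1L) * nRangeBins / M) + 1L
  out <- rowsum(m@data, grp, reorder = TRUE)
  newAxis <- as.numeric(tapply(m@rangeAxisM, grp, mean))
  echoMatrix(out, fastDtNs = m@fastDtNs * M / nRangeBins,
             slowFsHz = m@slowFsHz, rangeAxisM = newAxis,
             axisType = m@axisType)
}

## Centred moving average with symmetric truncation at the record edges:
## at sample i the half-width shrinks to min(h, i - 1, N - i), so no data
## are fabricated beyond the record. Returns the running-mean matrix.
.movingMean <- function(data, window) {
  N <- ncol(data)
  h <- window %/% 2L
  k <- pmin(h, seq_len(N) - 1L, N - seq_len(N))
  lo <- seq_len(N) - k
  hi <- seq_len(N) + k
  cs <- cbind(0, t(apply(data, 1L, cumsum)))
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(data))
}

#' Sliding-window static-clutter removal
#'
#' Subtracts from each range bin's slow-time signal its centred moving
#' average (window truncated symmetrically at the record edges). Echoes of
#' stationary objects such as walls are constant along slow time and map
#' exactly to zero; slow baseline drift is removed with them. The
#' operation is linear, so superposed signals are filtered independently.
#'
#' @param m an \linkS4class{EchoMatrix}.
#' @param clutterWindow sliding-window width in slow-time samples
#'   (default 100).
#' @return An \linkS4class{EchoMatrix} of identical shape.
#' @export
removeStaticClutter <- function(m, clutterWindow = 100L) {
  N <- ncol(m@data)
  if (N < clutterWindow)
    stop(sprintf("record length %d shorter than clutter window %d",
                 N, clutterWindow), call. = FALSE)
  out <- m
  out@data <- m@data - .movingMean(m@data, as.integer(clutterWindow))
  out
}

## Hamming-window linear-phase FIR low-pass taps via signal::fir1.
.firTaps <- function(lpOrder, lpCutoffHz, fsHz) {
  if (lpOrder < 2L) stop("FIR order must be >= 2", call. = FALSE)
  if (lpCutoffHz >= fsHz / 2)
    stop(sprintf("low-pass cutoff %g Hz is not below the Nyquist rate %g Hz",
                 lpCutoffHz, fsHz / 2), call. = FALSE)
  as.numeric(signal::fir1(lpOrder, lpCutoffHz / (fsHz / 2)))
}

#' FIR low-pass along slow time
#'
#' Filters every range bin's slow-time signal with a linear-phase
#' (Hamming-window) FIR low-pass and compensates the group delay of
#' order/2 samples, so the output stays phase-aligned with the input.
#' Respiration (a few tenths of a Hz) sits deep in the passband and is
#' preserved within a few percent; broadband receiver noise above the
#' cutoff is suppressed.
#'
#' @param m an \linkS4class{EchoMatrix} with a slow-time column axis.
#' @param lpCutoffHz cutoff frequency, Hz (default 4).
#' @param lpOrder filter order; taps = order + 1 (default 64, even so the
#'   group delay is an integer number of samples).
#' @return An \linkS4class{EchoMatrix} of identical shape.
#' @export
lowpassSlowTime <- function(m, lpCutoffHz = 4.0, lpOrder = 64L) {
  lpOrder <- as.integer(lpOrder)
  taps <- .firTaps(lpOrder, lpCutoffHz, m@slowFsHz)
  N <- ncol(m@data)
  delay <- lpOrder %/% 2L
  ## full convolution of every row, then take the delay-compensated span
  P <- stats::nextn(N + lpOrder, 2)
  H <- stats::fft(c(taps, rep(0, P - length(taps))))
  X <- stats::mvfft(rbind(t(m@data), matrix(0, P - N, nrow(m@data))))
  Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / P
  out <- m
  out@data <- t(Y[(delay + 1L):(delay + N), , drop = FALSE])
  out
}

#' Run the full preprocessing chain
#'
#' Distance accumulation, then sliding-window clutter removal, then the
#' FIR low-pass — turning a raw fast-time record into the compressed,
#' clutter-suppressed, band-limited matrix the auto-correlation and
#' wavelet-entropy stages consume. Each stage is linear, so the whole
#' chain is linear in the input matrix.
#'
#' @param m a raw \linkS4class{EchoMatrix}.
#' @param params a \linkS4class{PreprocessParams}.
#' @return An \linkS4class{EchoMatrix} with \code{params@nRangeBins} rows
#'   and the input's column count.
#' @export
preprocessEcho <- function(m, params = preprocessParams()) {
  validObject(params)
  m <- rangeAccumulate(m, params@nRangeBins)
  m <- removeStaticClutter(m, params@clutterWindow)
  lowpassSlowTime(m, params@lpCutoffHz, params@lpOrder)
}
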