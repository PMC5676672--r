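## Target calling on the entropy-vs-range profile: breathing targets carve
## contiguous pits whose width matches the torso footprint; trailing
## multipath carves wider, shallower depressions immediately behind a
## target. Pits are found against a robust relative threshold
## median(H) - k * MAD(H), gated by physical width, and width-failing pits
## right behind an accepted target are classified as ghosts.

#' Find candidate entropy pits
#'
#' A candidate pit is a maximal run of contiguous range bins, beyond the
#' blind range, whose entropy lies below the robust threshold
#' median(H) - k * MAD(H) (computed over the bins beyond the blind
#' range). Each pit is reported with its minimum location (ties broken
#' toward the nearer bin), interval edges, width and depth. Pit intervals
#' extend half a bin beyond the first and last sub-threshold bin centre,
#' so an n-bin pit has width n times the bin spacing.
#'
#' @param h an \linkS4class{EntropySpectrum}.
#' @param params a \linkS4class{DetectionParams}.
#' @return data.frame with columns range_m (pit minimum), center_m
#'   (interval midpoint — the more stable location estimate when the pit
#'   bottom is flat across the torso), lo_m, hi_m, width_m, h_min, n_bins
#'   (zero rows if the spectrum never dips below threshold), plus the
#'   threshold in attribute \code{"threshold"}.
#' @export
findEntropyPits <- function(h, params = detectionParams()) {
  validObject(params)
  beyond <- h@rangeAxisM > params@blindRangeM
  if (sum(beyond) < 8L)
    stop("need at least 8 range bins beyond the blind range", call. = FALSE)
  hv <- h@H
  sel <- hv[beyond]
  thr <- stats::median(sel) - params@pitK * stats::mad(sel)
  binW <- stats::median(diff(h@rangeAxisM))
  below <- beyond & (hv < thr)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  pits <- data.frame(range_m = numeric(0), center_m = numeric(0),
                     lo_m = numeric(0), hi_m = numeric(0),
                     width_m = numeric(0), h_min = numeric(0),
                     n_bins = integer(0))
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- hv[i0:i1]
    iMin <- i0 + which.min(seg) - 1L   # which.min takes the first (nearer) tie
    lo <- h@rangeAxisM[i0] - binW / 2
    hi <- h@rangeAxisM[i1] + binW / 2
    pits <- rbind(pits, data.frame(
      range_m = h@rangeAxisM[iMin],
      center_m = (lo + hi) / 2,
      lo_m = lo, hi_m = hi,
      width_m = (i1 - i0 + 1L) * binW,
      h_min = hv[iMin],
      n_bins = i1 - i0 + 1L))
  }
  attr(pits, "threshold") <- thr
  pits
}

#' Classify candidate pits into detections and rejections
#'
#' A pit is accepted iff its width lies within the torso gate
#' [minPitWidthM, maxPitWidthM]. A width-failing pit whose interval
#' starts within \code{ghostWindowM} behind an already accepted pit is
#' labelled \code{rejected_ghost} (trailing multipath re-radiating the
#' accepted target's respiration); any other width failure is
#' \code{rejected_width}. Classification proceeds in range order so a
#' ghost is always attributed to a nearer accepted target.
#'
#' @param pits data.frame from \code{\link{findEntropyPits}}.
#' @param params a \linkS4class{DetectionParams}.
#' @return A \linkS4class{DetectionReport}.
#' @export
classifyPits <- function(pits, params = detectionParams()) {
  validObject(params)
  thr <- attr(pits, "threshold")
  if (nrow(pits)) {
    pits <- pits[order(pits$range_m), , drop = FALSE]
    status <- character(nrow(pits))
    acceptedHi <- numeric(0)
    for (i in seq_len(nrow(pits))) {
      w <- pits$width_m[i]
      if (w >= params@minPitWidthM && w <= params@maxPitWidthM) {
        status[i] <- "accepted"
        acceptedHi <- c(acceptedHi, pits$hi_m[i])
      } else {
        gap <- pits$lo_m[i] - acceptedHi
        status[i] <- if (length(acceptedHi) &&
                         any(gap >= 0 & gap <= params@ghostWindowM))
          "rejected_ghost" else "rejected_width"
      }
    }
    pits$status <- status
  } else {
    pits$status <- character(0)
  }
  rownames(pits) <- NULL
  new("DetectionReport", detections = pits,
      threshold = if (is.null(thr)) NA_real_ else thr,
      params = list(blindRangeM = params@blindRangeM, pitK = params@pitK,
                    minPitWidthM = params@minPitWidthM,
                    maxPitWidthM = params@maxPitWidthM,
                    ghostWindowM = params@ghostWindowM))
}

#' Respiration-band power profile (energy-detection baseline)
#'
#' For every range bin, total periodogram power of the slow-time signal in
#' the respiration band (default 0.1-1 Hz). This is the classical
#' energy-spectrum detector that the wavelet-entropy statistic is compared
#' against: it sees the strong near target but a target in the shadowing
#' region leaves a peak negligible against the near target's.
#'
#' @param m a preprocessed \linkS4class{EchoMatrix} (slow-time axis).
#' @param bandHz two-element frequency band, Hz (default c(0.1, 1)).
#' @return data.frame with columns range_m and power.
#' @export
powerSpectrumProfile <- function(m, bandHz = c(0.1, 1.0)) {
  fs <- m@slowFsHz
  if (bandHz[2] > fs / 2)
    stop(sprintf("band edge %g Hz exceeds the Nyquist rate %g Hz",
                 bandHz[2], fs / 2), call. = FALSE)
  N <- ncol(m@data)
  freqs <- (seq_len(N) - 1L) * fs / N
  inBand <- freqs >= bandHz[1] & freqs <= bandHz[2]
  P <- Mod(stats::mvfft(t(m@data)))^2 / N
  data.frame(range_m = m@rangeAxisM, power = colSums(P[inBand, , drop = FALSE]))
}

#' Peak calling on the power profile
#'
#' Operationalises reading a power-spectrum plot: a peak counts as a
#' detection when it rises above both a robust noise floor
#' (median + k * MAD beyond the blind range) and a fraction
#' \code{relFrac} of the strongest peak — a shadowed target whose power is
#' orders of magnitude below the near target is invisible on the plot even
#' when it nominally exceeds the noise floor.
#'
#' @param profile data.frame from \code{\link{powerSpectrumProfile}}.
#' @param params a \linkS4class{DetectionParams} (blind range and k).
#' @param relFrac relative-to-maximum visibility threshold (default 0.05).
#' @return data.frame of peaks (range_m, power), possibly empty.
#' @export
findPowerPeaks <- function(profile, params = detectionParams(),
                           relFrac = 0.05) {
  beyond <- profile$range_m > params@blindRangeM
  p <- profile$power
  sel <- p[beyond]
  thr <- max(stats::median(sel) + params@pitK * stats::mad(sel),
             relFrac * max(sel))
  above <- beyond & (p > thr)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(range_m = numeric(0), power = numeric(0))
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    iMax <- i0 + which.max(p[i0:i1]) - 1L
    out <- rbind(out, data.frame(range_m = profile$range_m[iMax],
                                 power = p[iMax]))
  }
  attr(out, "threshold") <- thr
  out
}
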