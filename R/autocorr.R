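## Per-range-bin auto-correlation. A periodic respiration signature is
## correlated with itself at every lag, while receiver noise is
## uncorrelated and piles its energy into the zero-lag sample, so the
## lag-domain signal has a far cleaner line spectrum than the raw record.

.autocorrRaw <- function(data) {
  ## rows = range bins; returns matrix of raw lag sums, same shape
  N <- ncol(data)
  P <- stats::nextn(2L * N, 2)
  X <- stats::mvfft(rbind(t(data), matrix(0, P - N, nrow(data))))
  C <- Re(stats::mvfft(Mod(X)^2, inverse = TRUE)) / P
  t(C[seq_len(N), , drop = FALSE])
}

#' Auto-correlation of one slow-time vector
#'
#' Estimates R(k) = E[x(t) x(t - k)] by the time average over the single
#' available realisation. The biased estimator divides every lag sum by N,
#' which tapers large lags and guarantees |R(k)| <= R(0) together with a
#' nonnegative spectrum; the unbiased estimator divides by N - k.
#'
#' @param x numeric slow-time vector with at least 2 samples.
#' @param params an \linkS4class{AutocorrParams}.
#' @return Numeric vector R(0), R(1), ..., R(maxLag).
#' @examples
#' autocorrelate(sin(2 * pi * 0.25 * (0:255) / 64))[1:4]
#' @export
autocorrelate <- function(x, params = autocorrParams()) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 2L) stop("autocorrelation needs at least 2 samples", call. = FALSE)
  maxLag <- if (is.na(params@maxLag)) N - 1L else params@maxLag
  if (maxLag < 1L || maxLag > N - 1L)
    stop("maxLag must be in [1, N - 1]", call. = FALSE)
  raw <- .autocorrRaw(matrix(x, nrow = 1L))[1L, seq_len(maxLag + 1L)]
  r <- switch(params@estimator,
    biased = raw / N,
    unbiased = raw / (N - 0:maxLag)
  )
  if (params@normalize && r[1L] != 0) r <- r / r[1L]
  r
}

#' Auto-correlation of every range bin
#'
#' Applies \code{\link{autocorrelate}} independently to each row of the
#' (preprocessed) echo matrix. The slow-time column axis is replaced by a
#' lag axis at the same sampling rate; range metadata are preserved.
#'
#' @param m an \linkS4class{EchoMatrix} with a slow-time column axis.
#' @param params an \linkS4class{AutocorrParams}.
#' @return An \linkS4class{EchoMatrix} with \code{axisType = "lag"}.
#' @export
autocorrelateMatrix <- function(m, params = autocorrParams()) {
  N <- ncol(m@data)
  if (N < 2L) stop("autocorrelation needs at least 2 samples", call. = FALSE)
  maxLag <- if (is.na(params@maxLag)) N - 1L else params@maxLag
  if (maxLag < 1L || maxLag > N - 1L)
    stop("maxLag must be in [1, N - 1]", call. = FALSE)
  raw <- .autocorrRaw(m@data)[, seq_len(maxLag + 1L), drop = FALSE]
  out <- switch(params@estimator,
    biased = raw / N,
    unbiased = sweep(raw, 2L, N - 0:maxLag, `/`)
  )
  if (params@normalize) {
    r0 <- out[, 1L]
    bad <- which(r0 == 0)
    if (length(bad))
      warning("zero-energy rows left unnormalized: ",
              paste(bad, collapse = ", "))
    r0[r0 == 0] <- 1
    out <- out / r0
  }
  res <- m
  res@data <- out
  res@axisType <- "lag"
  res
}
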