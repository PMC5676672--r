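## Dyadic discrete wavelet transform, periodized (circular) orthogonal
## filter bank. With an orthonormal conjugate-quadrature filter pair the
## circular analysis operator is exactly orthogonal at every even signal
## length, so Parseval holds exactly (sum of squared coefficients equals
## the squared signal norm) and the transpose gives perfect reconstruction.

## Daubechies scaling (low-pass) filters, dbN = N vanishing moments,
## 2N taps, sum = sqrt(2). Standard published constants.
.DB_FILTERS <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108,
          0.00055384220116149613, -0.03158203931748603, 0.027522865530305727,
          0.097501605587323043, -0.12976686756726194, -0.22626469396543983,
          0.31525035170919763, 0.75113390802109536, 0.49462389039845306,
          0.11154074335010947),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933,
          -0.00039174037337694705, -0.0048703529934515741,
          0.0087460940474057766, 0.013981027917398282, -0.044088253930794755,
          -0.017369301001807547, 0.12874742662047847, 0.00047248457391328279,
          -0.28401554296154691, -0.015829105256349306, 0.58535468365420673,
          0.67563073629728976, 0.31287159091429995, 0.054415842243104008)
)

waveletFilters <- function(waveletName) {
  lo <- .DB_FILTERS[[waveletName]]
  if (is.null(lo))
    stop("unknown wavelet '", waveletName, "'; available: ",
         paste(names(.DB_FILTERS), collapse = ", "), call. = FALSE)
  L <- length(lo)
  ## alternating flip gives the orthonormal high-pass (wavelet) filter
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi)
}

## One circular analysis step: x (even length) -> list(a, d), each n/2 long.
.dwtStep <- function(x, flt) {
  n <- length(x)
  L <- length(flt$lo)
  idx <- (outer(2L * (seq_len(n %/% 2L) - 1L), seq_len(L) - 1L, `+`) %% n) + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L)
  list(a = as.numeric(xm %*% flt$lo), d = as.numeric(xm %*% flt$hi))
}

## Transpose of .dwtStep: (a, d) -> x of length 2 * length(a).
.idwtStep <- function(a, d, flt) {
  n <- 2L * length(a)
  L <- length(flt$lo)
  idx <- (outer(2L * (seq_len(n %/% 2L) - 1L), seq_len(L) - 1L, `+`) %% n) + 1L
  contrib <- outer(a, flt$lo) + outer(d, flt$hi)
  as.numeric(rowsum(as.numeric(contrib), as.numeric(idx)))
}

#' Dyadic discrete wavelet decomposition
#'
#' Iterates a two-channel orthogonal filter bank on the approximation: the
#' signal is split into a detail band D1 and approximation A1, A1 into D2
#' and A2, and so on for \code{nLevels} steps. Boundary handling is
#' circular (periodized), which keeps the transform exactly orthonormal:
#' the summed squared coefficients equal the squared signal norm and
#' \code{\link{dwtReconstruct}} inverts the transform to machine precision.
#'
#' @param x numeric vector; its length must be divisible by
#'   \code{2^nLevels}.
#' @param params a \linkS4class{WaveletParams}.
#' @return A \linkS4class{WaveletDecomposition} with subbands
#'   \code{D1..DJ} (finest to coarsest detail) and \code{AJ}.
#' @examples
#' d <- dwtDecompose(sin(2 * pi * 0.25 * (0:511) / 64), waveletParams())
#' lengths(waveletCoeffs(d))
#' @export
dwtDecompose <- function(x, params = waveletParams()) {
  x <- as.numeric(x)
  n <- length(x)
  J <- params@nLevels
  if (n < 2^J || n %% 2^J != 0L) {
    maxJ <- 0L
    m <- n
    while (m %% 2L == 0L && m >= 2L) { maxJ <- maxJ + 1L; m <- m %/% 2L }
    stop(sprintf(
      "signal of length %d does not support a depth-%d dyadic DWT (maximum feasible depth: %d)",
      n, J, maxJ), call. = FALSE)
  }
  flt <- waveletFilters(params@waveletName)
  coeffs <- vector("list", J + 1L)
  names(coeffs) <- c(paste0("D", seq_len(J)), paste0("A", J))
  a <- x
  for (j in seq_len(J)) {
    s <- .dwtStep(a, flt)
    coeffs[[j]] <- s$d
    a <- s$a
  }
  coeffs[[J + 1L]] <- a
  new("WaveletDecomposition", coeffs = coeffs,
      waveletName = params@waveletName, nLevels = J, nOrig = as.integer(n))
}

#' Inverse dyadic discrete wavelet transform
#'
#' @param d a \linkS4class{WaveletDecomposition}.
#' @return The reconstructed numeric vector of length \code{nOrig}.
#' @export
dwtReconstruct <- function(d) {
  flt <- waveletFilters(d@waveletName)
  J <- d@nLevels
  a <- d@coeffs[[J + 1L]]
  for (j in rev(seq_len(J)))
    a <- .idwtStep(a, d@coeffs[[j]], flt)
  a
}
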