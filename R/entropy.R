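## Wavelet-entropy statistic: distribute each lag-domain vector's energy
## across the J detail subbands plus the level-J approximation, normalise
## to a probability vector, and take the Shannon entropy. A narrow-band
## respiration signature concentrates its energy in one band (low
## entropy); broadband noise spreads it across all bands (entropy near
## the ceiling ln(J + 1)).

## Split the coefficients of each subband into nWindows contiguous chunks
## aligned with non-overlapping temporal windows of the input.
.windowCounts <- function(d, nWindows) {
  lens <- lengths(d@coeffs)
  if (any(lens %% nWindows != 0L))
    stop(sprintf(
      "window length incompatible with subband lengths (%s) for %d windows",
      paste(lens, collapse = ", "), nWindows), call. = FALSE)
  lens %/% nWindows
}

#' Windowed subband energies
#'
#' For each non-overlapping temporal window i and subband j, computes the
#' energy sum of squared coefficients falling in that window. In
#' \code{"mean_per_coeff"} mode the sum is divided by the coefficient
#' count N_j(i) of the band in the window — an average energy per
#' coefficient, which makes the J + 1 bands of white noise equally
#' energetic and maximises the contrast against a narrow-band signature.
#' \code{"raw_sum"} leaves the plain sums, whose white-noise distribution
#' instead follows the halving bandwidth of the dyadic bands.
#'
#' @param d a \linkS4class{WaveletDecomposition}.
#' @param params a \linkS4class{WaveletParams}; \code{windowLen} (in input
#'   samples) must divide the signal length and be a multiple of
#'   \code{2^nLevels} so each band splits evenly across windows.
#' @return An \linkS4class{EnergyDistribution} (P unfilled).
#' @export
subbandEnergies <- function(d, params = waveletParams()) {
  n <- d@nOrig
  L <- if (is.na(params@windowLen)) n else params@windowLen
  if (L < 1L || n %% L != 0L)
    stop(sprintf("window length %d must divide the signal length %d", L, n),
         call. = FALSE)
  nWindows <- n %/% L
  if (L %% 2^d@nLevels != 0L)
    stop(sprintf("window length %d must be a multiple of 2^%d", L, d@nLevels),
         call. = FALSE)
  perWin <- .windowCounts(d, nWindows)
  nb <- length(d@coeffs)
  E <- matrix(0, nrow = nWindows, ncol = nb,
              dimnames = list(NULL, names(d@coeffs)))
  nC <- matrix(rep(perWin, each = nWindows), nrow = nWindows,
               dimnames = list(NULL, names(d@coeffs)))
  for (j in seq_len(nb)) {
    c2 <- d@coeffs[[j]]^2
    grp <- rep(seq_len(nWindows), each = perWin[j])
    E[, j] <- as.numeric(rowsum(c2, grp))
  }
  if (params@energyMode == "mean_per_coeff") E <- E / nC
  new("EnergyDistribution", E = E, nCoeffs = nC, eTotal = rowSums(E),
      P = matrix(numeric(0), 0, 0), mode = params@energyMode)
}

#' Relative subband energies
#'
#' Fills the probability vector P_j = E_j / sum_j E_j per window. The
#' rows of P sum to one exactly (to rounding); they are invariant under
#' any positive rescaling of the input signal.
#'
#' @param e an \linkS4class{EnergyDistribution} from
#'   \code{\link{subbandEnergies}}.
#' @return The same object with \code{P} filled.
#' @export
relativeEnergies <- function(e) {
  if (any(e@eTotal <= 0))
    stop(sprintf(
      "zero total energy in window(s) %s: relative energy distribution undefined",
      paste(which(e@eTotal <= 0), collapse = ", ")), call. = FALSE)
  e@P <- e@E / e@eTotal
  validObject(e)
  e
}

#' Shannon entropy of a subband energy distribution
#'
#' H(P) = -sum_j P_j ln(P_j) in nats, with the convention 0 ln 0 = 0.
#' Bounded by 0 (all energy in one band: a fully ordered signal) and
#' ln(J + 1) (uniform spread: maximal disorder).
#'
#' @param p either a probability vector or an
#'   \linkS4class{EnergyDistribution} with \code{P} filled (one entropy
#'   per window is returned).
#' @param tol tolerance on sum(P) == 1 and P >= 0 (default 1e-8).
#' @return Entropy value(s) in nats.
#' @examples
#' shannonWaveletEntropy(c(0.5, 0.25, 0.25))  # 1.0397...
#' @export
shannonWaveletEntropy <- function(p, tol = 1e-8) {
  if (is(p, "EnergyDistribution")) {
    if (nrow(p@P) == 0L)
      stop("relative energies not filled; call relativeEnergies() first",
           call. = FALSE)
    return(apply(p@P, 1L, shannonWaveletEntropy, tol = tol))
  }
  p <- as.numeric(p)
  if (any(p < -tol)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("probabilities sum to %.12g, not 1", sum(p)), call. = FALSE)
  p <- pmax(p, 0)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) + 0   # + 0 turns IEEE -0 into 0
}

#' Wavelet-entropy spectrum over range
#'
#' For every range bin of an auto-correlated echo matrix: dyadic DWT of
#' the lag-domain vector, windowed subband energies, relative energies,
#' Shannon entropy per window, combined across windows (mean or max).
#' Bins with zero total energy carry the ceiling ln(J + 1) — no structure
#' reads as maximal disorder — and are flagged in \code{zeroEnergy}.
#'
#' @param m an \linkS4class{EchoMatrix} (typically \code{axisType "lag"}).
#' @param params a \linkS4class{WaveletParams}.
#' @return An \linkS4class{EntropySpectrum} with one H value per bin.
#' @export
entropySpectrum <- function(m, params = waveletParams()) {
  validObject(params)
  nb <- nrow(m@data)
  H <- numeric(nb)
  zero <- logical(nb)
  ceilH <- log(params@nLevels + 1)
  for (i in seq_len(nb)) {
    x <- m@data[i, ]
    if (all(x == 0) || sum(x^2) == 0) {
      H[i] <- ceilH
      zero[i] <- TRUE
      next
    }
    d <- dwtDecompose(x, params)
    e <- relativeEnergies(subbandEnergies(d, params))
    hw <- shannonWaveletEntropy(e)
    H[i] <- switch(params@windowCombine, mean = mean(hw), max = max(hw))
  }
  if (any(zero))
    message("zero-energy range bin(s) at ",
            paste(sprintf("%.2f m", m@rangeAxisM[zero]), collapse = ", "),
            "; entropy set to ceiling ln(J+1)")
  new("EntropySpectrum", H = H, rangeAxisM = m@rangeAxisM, zeroEnergy = zero,
      params = list(wavelet = params@waveletName, nLevels = params@nLevels,
                    windowLen = params@windowLen,
                    energyMode = params@energyMode,
                    windowCombine = params@windowCombine))
}
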