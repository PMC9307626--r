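#' Fourier transform a FID into a 1D spectrum
#'
#' Standard 1D processing: the first time-domain point is halved (DC
#' correction for the half-sample offset of the first point), the FID is
#' zero-filled, discrete-Fourier transformed, scaled by `2 * dwell` so that
#' the absorptive integral of a resonance equals its time-domain amplitude
#' (area), and mapped onto a descending ppm axis computed from the
#' transmitter frequency and carrier. No apodization is applied: the fit
#' model absorbs the linewidth, and windowing would bias peak areas, which
#' are the quantity of record here.
#'
#' With this scaling, Parseval's identity holds exactly between the
#' DC-corrected time series and the spectrum:
#' `sum(|fid|^2) * dwell = sum(|spec|^2) * dnu`.
#'
#' @param fid a [Fid-class].
#' @param zeroFillFactor integer >= 1; the transform length is
#'   `zeroFillFactor * nPoints`. Zero-filling interpolates the spectrum
#'   for display; for quantitative fitting use 1, since interpolated
#'   points carry correlated noise and would overstate the information
#'   content of the record.
#' @return A [Spectrum1D-class] with `noiseSd = NA` (estimate it with
#'   [estimateNoise()]).
#' @examples
#' truth <- groundTruthSpectrum(foldedFraction = 0.59)
#' spec <- fourierTransform(simulateFid(truth, seed = 1))
#' @export
fourierTransform <- function(fid, zeroFillFactor = 2L) {
  stopifnot(is(fid, "Fid"))
  if (zeroFillFactor < 1) stop("zeroFillFactor must be >= 1", call. = FALSE)
  x <- fid@points
  x[1] <- x[1] / 2
  n <- length(x)
  m <- as.integer(round(n * zeroFillFactor))
  xp <- c(x, complex(real = numeric(m - n)))
  vals <- 2 * fid@dwell * fft(xp)
  k <- seq_len(m) - 1L
  hz <- ifelse(k < m / 2, k, k - m) / (m * fid@dwell)
  ppm <- fid@carrier + hz / fid@sfo
  ord <- order(ppm, decreasing = TRUE)
  new("Spectrum1D", values = vals[ord], axis = ppm[ord], sfo = fid@sfo,
      noiseSd = NA_real_)
}

#' Estimate spectral noise by robust scale of the baseline
#'
#' Computes `1.4826 * MAD` of the real part of the spectrum outside the
#' given exclusion windows (signal regions). At least 50 baseline points
#' are required.
#'
#' @param spec a [Spectrum1D-class].
#' @param exclusionWindows list of length-2 numeric vectors giving ppm
#'   intervals to exclude (order within a window is irrelevant).
#' @return numeric noise standard deviation (a.u.).
#' @examples
#' truth <- groundTruthSpectrum(foldedFraction = 0.5, noiseSd = 0.1)
#' spec <- fourierTransform(simulateFid(truth, seed = 1))
#' estimateNoise(spec, list(c(-63, -61)))
#' @export
estimateNoise <- function(spec, exclusionWindows = list()) {
  stopifnot(is(spec, "Spectrum1D"))
  keep <- rep(TRUE, length(spec@axis))
  for (w in exclusionWindows) {
    lo <- min(w); hi <- max(w)
    keep <- keep & !(spec@axis >= lo & spec@axis <= hi)
  }
  if (sum(keep) < 50L)
    stop("insufficient baseline: fewer than 50 points outside exclusion windows",
         call. = FALSE)
  mad(Re(spec@values[keep]), center = median(Re(spec@values[keep])))
}

#' Attach a noise estimate to a spectrum
#'
#' Convenience: runs [estimateNoise()] and stores the result in the
#' `noiseSd` slot.
#'
#' @inheritParams estimateNoise
#' @return The spectrum with `noiseSd` set.
#' @export
withNoiseEstimate <- function(spec, exclusionWindows = list()) {
  spec@noiseSd <- estimateNoise(spec, exclusionWindows)
  spec
}
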