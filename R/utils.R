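# Gyromagnetic ratios relative to 1H, used for ppm <-> Hz conversions on
# heteronuclear axes referenced to the 1H transmitter frequency.
.gyromagneticRatios <- c("1H" = 1, "19F" = 0.9407, "13C" = 0.251450,
                         "15N" = 0.101329)

#' Convert between ppm and Hz on a given transmitter frequency
#'
#' A chemical-shift difference of `delta` ppm corresponds to
#' `delta * sfo` Hz on a `sfo` MHz axis.
#'
#' @param delta shift difference in ppm (`ppmToHz`) or Hz (`hzToPpm`).
#' @param sfo transmitter frequency in MHz.
#' @return numeric, the converted difference.
#' @examples
#' ppmToHz(0.8, 470.4)
#' hzToPpm(376.3, 470.4)
#' @export
ppmToHz <- function(delta, sfo) delta * sfo

#' @rdname ppmToHz
#' @export
hzToPpm <- function(delta, sfo) delta / sfo

#' Frequency separation of two resonances
#'
#' Converts a chemical-shift separation in ppm into s^-1, given the 1H
#' transmitter frequency of the instrument and the observed nucleus. Used
#' to check the slow-exchange condition k_ex << |delta_U - delta_F|.
#'
#' @param deltaPpm separation in ppm.
#' @param sfo1H 1H transmitter frequency in MHz (e.g. 500.13).
#' @param nucleus nucleus label with a configured gyromagnetic ratio
#'   ("1H", "19F", "13C", "15N").
#' @return separation in s^-1.
#' @examples
#' frequencySeparation(0.8, 500.13, "19F") # ~376 s^-1
#' @export
frequencySeparation <- function(deltaPpm, sfo1H, nucleus = "19F") {
  if (!nucleus %in% names(.gyromagneticRatios))
    stop("unknown nucleus '", nucleus, "'; configured: ",
         paste(names(.gyromagneticRatios), collapse = ", "), call. = FALSE)
  deltaPpm * sfo1H * .gyromagneticRatios[[nucleus]]
}

# Wrap angles into (-pi, pi].
wrapPhase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Split-Rhat convergence diagnostic: each chain is split in half and the
# classical potential scale reduction factor is computed over the 2*m half
# chains (rank-free version).
splitRhat <- function(draws, chainId) {
  chains <- split(draws, chainId)
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[seq_len(n) + n])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Quadratic-interpolated seed splitting so that one user seed drives several
# independent generators while staying below 2^31.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
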