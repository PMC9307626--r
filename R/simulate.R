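#' Ground truth for a synthetic two-state 19F spectrum
#'
#' Builds the resonance description of a slow-exchange folded/unfolded
#' nascent-chain spectrum. Defaults emulate the experimental regime: two
#' narrow peaks separated by 0.8 ppm on a 470.4 MHz 19F axis with 60-150 Hz
#' linewidths, optionally a broad component (FWHM >= 500 Hz), and complex
#' Gaussian time-domain noise.
#'
#' @param foldedFraction fraction of the narrow-peak area in the folded (F)
#'   state, in `[0, 1]`.
#' @param totalArea combined area of the U and F peaks (a.u.).
#' @param positions named numeric `c(U = ..., F = ...)` in ppm.
#' @param fwhm named numeric `c(U = ..., F = ...)` in Hz.
#' @param phase phase of both narrow peaks, rad.
#' @param broad `NULL`, or numeric `c(position, fwhm, area)` for a broad
#'   background component (fwhm >= 500 Hz); excluded from `foldedFraction`.
#' @param noiseSd standard deviation of the complex Gaussian noise per
#'   time-domain point (each of the real/imaginary channels).
#' @return A [GroundTruthSpectrum-class].
#' @examples
#' groundTruthSpectrum(foldedFraction = 0.59)
#' @export
groundTruthSpectrum <- function(foldedFraction, totalArea = 1,
                                positions = c(U = -62.4, F = -61.6),
                                fwhm = c(U = 70, F = 90), phase = 0,
                                broad = NULL, noiseSd = 0) {
  stopifnot(foldedFraction >= 0, foldedFraction <= 1, totalArea >= 0)
  peaks <- data.frame(
    position = as.numeric(positions[c("U", "F")]),
    fwhm = as.numeric(fwhm[c("U", "F")]),
    area = totalArea * c(1 - foldedFraction, foldedFraction),
    phase = rep(phase, length.out = 2), label = c("U", "F"),
    stringsAsFactors = FALSE)
  broadDf <- NULL
  if (!is.null(broad)) {
    broadDf <- data.frame(position = broad[1], fwhm = broad[2],
                          area = broad[3], phase = 0, label = "broad",
                          stringsAsFactors = FALSE)
  }
  new("GroundTruthSpectrum", peaks = peaks, broad = broadDf,
      foldedFraction = foldedFraction, noiseSd = noiseSd)
}

# All peaks of a ground truth (narrow + broad) as one data.frame.
.allTruthPeaks <- function(truth) {
  if (is.null(truth@broad)) truth@peaks else rbind(truth@peaks, truth@broad)
}

#' Simulate a free induction decay
#'
#' Generates the complex time series
#' `s(t) = sum_k a_k exp(i(2 pi nu_k t + phi_k)) exp(-pi FWHM_k t)`
#' plus i.i.d. circular complex Gaussian noise, sampled on the acquisition
#' grid. Frequencies `nu_k` are offsets from the carrier in Hz
#' (`(position - carrier) * sfo`). At `t = 0` the noiseless signal equals
#' the total area, so a peak's area is its time-domain amplitude.
#'
#' @param truth a [GroundTruthSpectrum-class].
#' @param acq an [AcquisitionParams-class]; the default is the 19F setup
#'   (470.4 MHz, 350 ms acquisition over 4096 points).
#' @param seed integer seed; identical truth + seed gives bit-identical
#'   output.
#' @param nScans scan count stored in the record's metadata.
#' @return A [Fid-class].
#' @examples
#' fid <- simulateFid(groundTruthSpectrum(0.59), seed = 7)
#' @export
simulateFid <- function(truth, acq = acquisitionParams(), seed = NULL,
                        nScans = 1L) {
  stopifnot(is(truth, "GroundTruthSpectrum"), is(acq, "AcquisitionParams"))
  t <- (seq_len(acq@nPoints) - 1L) * acq@dwell
  s <- complex(real = numeric(acq@nPoints))
  pk <- .allTruthPeaks(truth)
  for (k in seq_len(nrow(pk))) {
    nu <- (pk$position[k] - acq@carrier) * acq@sfo
    s <- s + pk$area[k] *
      exp(complex(imaginary = 2 * pi * nu * t + pk$phase[k])) *
      exp(-pi * pk$fwhm[k] * t)
  }
  if (truth@noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + complex(real = rnorm(acq@nPoints, sd = truth@noiseSd),
                     imaginary = rnorm(acq@nPoints, sd = truth@noiseSd))
  }
  new("Fid", points = s, dwell = acq@dwell, sfo = acq@sfo,
      carrier = acq@carrier, nucleus = "19F", nScans = as.integer(nScans))
}

#' Time-domain noise level for a target spectral SNR
#'
#' Returns the per-point time-domain noise standard deviation that gives
#' approximately the requested signal-to-noise ratio on the tallest narrow
#' peak after [fourierTransform()] (height `2a/(pi w)`, spectral noise
#' `2 * dwell * sigma_t * sqrt(nPoints)`).
#'
#' @param truth a [GroundTruthSpectrum-class].
#' @param acq an [AcquisitionParams-class].
#' @param snr target signal-to-noise ratio of the dominant peak.
#' @return numeric noise sd to pass to [groundTruthSpectrum()].
#' @examples
#' tr <- groundTruthSpectrum(0.59)
#' noiseForSnr(tr, snr = 20)
#' @export
noiseForSnr <- function(truth, acq = acquisitionParams(), snr = 20) {
  h <- max(2 * truth@peaks$area / (pi * truth@peaks$fwhm))
  h / (snr * 2 * acq@dwell * sqrt(acq@nPoints))
}

#' Simulate a fast-exchange chemical-shift-perturbation series
#'
#' Observed shifts are the population-weighted average of the bound and
#' unbound reference shifts, `delta_obs = p delta_b + (1 - p) delta_ub`,
#' plus Gaussian noise.
#'
#' @param pBound numeric vector of bound fractions, each in `[0, 1]`.
#' @param deltaBound,deltaUnbound reference shifts in ppm (must differ).
#' @param noiseSd Gaussian noise sd on the observed shift, ppm.
#' @param seed integer seed.
#' @param variant optional character labels, recycled.
#' @return data.frame of binding observations with columns `variant`,
#'   `delta_obs`, `delta_unbound`, `delta_bound`, `sd_obs`, `p_true`.
#' @examples
#' simulateCspSeries(c(0, 0.5, 1), deltaBound = 8.50, deltaUnbound = 8.40)
#' @export
simulateCspSeries <- function(pBound, deltaBound, deltaUnbound, noiseSd = 0,
                              seed = NULL, variant = NULL) {
  if (any(pBound < 0 | pBound > 1))
    stop("bound fractions must lie in [0, 1]", call. = FALSE)
  if (deltaBound == deltaUnbound)
    stop("deltaBound and deltaUnbound must differ", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- pBound * deltaBound + (1 - pBound) * deltaUnbound
  if (noiseSd > 0) obs <- obs + rnorm(length(pBound), sd = noiseSd)
  data.frame(
    variant = if (is.null(variant)) sprintf("obs%02d", seq_along(pBound))
              else rep(variant, length.out = length(pBound)),
    delta_obs = obs, delta_unbound = deltaUnbound, delta_bound = deltaBound,
    sd_obs = noiseSd, p_true = pBound, stringsAsFactors = FALSE)
}

#' Simulate folded/unfolded peak-volume tables across linker lengths
#'
#' The folded-channel relative intensity follows a logistic in linker
#' length `L` with midpoint `onsetL`; the unfolded channel is its
#' complement. Multiplicative concentration noise is drawn once per length
#' and applied identically to both channels, emulating shared
#' nascent-chain concentration errors.
#'
#' @param onsetL logistic midpoint in residues.
#' @param steepness logistic steepness per residue; `Inf` gives a step.
#' @param lengths strictly increasing integer vector of linker lengths.
#' @param concNoiseFrac fractional sd of the multiplicative concentration
#'   noise.
#' @param seed integer seed.
#' @param markersU,markersF marker residue ids for each channel.
#' @param nScans scan count per measurement.
#' @param scale overall volume scale (a.u.).
#' @return list with elements `U` and `F`, each a peak-volume data.frame
#'   (columns `residue`, `linker_L`, `volume`, `volume_sd`, `n_scans`,
#'   `concentration`, `conc_sd`) with a `"channel"` attribute, plus
#'   `truth`, the noiseless folded fraction per length.
#' @examples
#' simulateIntensityProfile(onsetL = 34, lengths = c(31, 34, 37, 42, 67))
#' @export
simulateIntensityProfile <- function(onsetL = 34, steepness = 0.5,
                                     lengths = c(21, 31, 34, 37, 42, 67),
                                     concNoiseFrac = 0, seed = NULL,
                                     markersU = c(682, 683, 694),
                                     markersF = c(674, 695, 738, 743),
                                     nScans = 256L, scale = 100) {
  if (!length(lengths)) stop("lengths must be non-empty", call. = FALSE)
  if (any(diff(lengths) <= 0))
    stop("lengths must be strictly increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pF <- if (is.infinite(steepness)) as.numeric(lengths > onsetL)
        else 1 / (1 + exp(-steepness * (lengths - onsetL)))
  conc <- 1 + if (concNoiseFrac > 0)
    rnorm(length(lengths), sd = concNoiseFrac) else numeric(length(lengths))
  mk <- function(markers, frac, channel) {
    df <- expand.grid(residue = markers, linker_L = lengths,
                      KEEP.OUT.ATTRS = FALSE)
    idx <- match(df$linker_L, lengths)
    df$volume <- scale * frac[idx] * conc[idx] * nScans
    df$volume_sd <- 0
    df$n_scans <- nScans
    df$concentration <- conc[idx]
    df$conc_sd <- concNoiseFrac
    attr(df, "channel") <- channel
    df
  }
  list(U = mk(markersU, 1 - pF, "U"), F = mk(markersF, pF, "F"),
       truth = data.frame(linker_L = lengths, p_f = pF))
}

#' Specification of a toy nascent-chain + tunnel ensemble
#'
#' Describes the synthetic coordinate ensembles used to test the structural
#' statistics operators: a fixed pseudo-atom cylinder as the tunnel wall
#' (the ribosome is frozen across frames, as in the underlying
#' simulations), two small protein-loop clusters protruding into it, and a
#' self-avoiding jointed nascent chain threaded along the axis whose
#' per-residue orientational dispersion follows `mobility`.
#'
#' @param nFrames number of frames (>= 1).
#' @param ncLength number of nascent-chain residues.
#' @param mobility per-residue dispersion in `[0, 1]`: 0 = rigid
#'   (identical frames), 1 = isotropic carbonyl orientations.
#' @param tunnelRadius wall cylinder radius, Angstrom.
#' @param tunnelLength wall cylinder length, Angstrom.
#' @param seed integer seed.
#' @return validated list of class `"EnsembleSpec"`.
#' @examples
#' ensembleSpec(nFrames = 5, ncLength = 8)
#' @export
ensembleSpec <- function(nFrames = 50L, ncLength = 12L,
                         mobility = rep(0.2, ncLength), tunnelRadius = 13,
                         tunnelLength = 45, seed = 1L) {
  if (nFrames < 1L) stop("nFrames must be >= 1", call. = FALSE)
  mobility <- rep(mobility, length.out = ncLength)
  if (any(mobility < 0 | mobility > 1))
    stop("mobility values must lie in [0, 1]", call. = FALSE)
  structure(list(nFrames = as.integer(nFrames),
                 ncLength = as.integer(ncLength), mobility = mobility,
                 tunnelRadius = tunnelRadius, tunnelLength = tunnelLength,
                 seed = as.integer(seed)), class = "EnsembleSpec")
}

# Fixed tunnel wall: rings of pseudo-atoms plus two loop clusters.
.tunnelWall <- function(radius, len) {
  zs <- seq(0, len, by = 3)
  ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
  wall <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(ang), radius * sin(ang), z)))
  loop23 <- cbind(c(radius - 2, radius - 4, radius - 6),
                  c(0, 0.5, 1), c(28, 28.5, 29))
  loop24 <- cbind(c(-(radius - 2), -(radius - 4), -(radius - 6)),
                  c(0, -0.5, -1), c(38, 38.5, 39))
  list(wall = wall, loop23 = loop23, loop24 = loop24)
}

#' Simulate a toy nascent-chain ensemble in a rigid tunnel
#'
#' Places a self-avoiding jointed chain (one CA, C and O pseudo-atom per
#' residue) along the axis of a fixed pseudo-atom cylinder and generates
#' frames in which residue positions and carbonyl C-O orientations are
#' perturbed according to the per-residue `mobility`: at 0 every frame is
#' identical; at 1 the carbonyl orientation is drawn uniformly on the
#' sphere. Coordinates are rounded to 0.001 Angstrom so that the
#' multi-model PDB round trip is lossless.
#'
#' @param spec an [ensembleSpec()].
#' @return A [StructureEnsemble-class] with roles `"NC"`, `"rRNA:wall"`,
#'   `"protein:uL23"`, `"protein:uL24"`.
#' @examples
#' ens <- simulateEnsemble(ensembleSpec(nFrames = 3, ncLength = 6))
#' nFrames(ens)
#' @export
simulateEnsemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  set.seed(spec$seed)
  w <- .tunnelWall(spec$tunnelRadius, spec$tunnelLength)
  obstacles <- rbind(w$wall, w$loop23, w$loop24)
  n <- spec$ncLength

  placeChain <- function() {
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- c(0, 0, 2)
    for (i in seq_len(n - 1L)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        dir <- c(rnorm(2, sd = 0.35), 1)
        dir <- dir / sqrt(sum(dir^2))
        cand <- ca[i, ] + 3.8 * dir
        if (sqrt(sum(cand[1:2]^2)) > spec$tunnelRadius - 3) next
        if (cand[3] < 0) next
        if (min(sqrt(colSums((t(obstacles) - cand)^2))) < 3.0) next
        if (i > 1L &&
            min(sqrt(colSums((t(ca[seq_len(i - 1L), , drop = FALSE]) -
                              cand)^2))) < 3.8) next
        ok <- TRUE
        break
      }
      if (!ok) return(NULL)
      ca[i + 1L, ] <- cand
    }
    ca
  }
  ca <- NULL
  for (restart in seq_len(20L)) {
    ca <- placeChain()
    if (!is.null(ca)) break
  }
  if (is.null(ca))
    stop("generation failure: could not place the chain without clashes",
         call. = FALSE)

  # fixed reference carbonyl orientations, helically staggered
  psi <- (seq_len(n) - 1L) * 100 * pi / 180
  u0 <- cbind(cos(psi), sin(psi), 0)

  atomsPerRes <- 3L
  ncAtoms <- n * atomsPerRes
  wallXyz <- obstacles
  nWall <- nrow(wallXyz)
  nAtoms <- ncAtoms + nWall
  coords <- array(NA_real_, c(nAtoms, 3L, spec$nFrames))
  randUnit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (f in seq_len(spec$nFrames)) {
    xyz <- matrix(NA_real_, ncAtoms, 3L)
    for (i in seq_len(n)) {
      m <- spec$mobility[i]
      caf <- ca[i, ] + if (m > 0) m * 1.2 * rnorm(3) else 0
      u <- if (m > 0) {
        v <- (1 - m) * u0[i, ] + m * randUnit()
        v / sqrt(sum(v^2))
      } else u0[i, ]
      r <- (i - 1L) * atomsPerRes
      xyz[r + 1L, ] <- caf
      xyz[r + 2L, ] <- caf + 1.50 * u
      xyz[r + 3L, ] <- caf + (1.50 + 1.23) * u
    }
    coords[, , f] <- round(rbind(xyz, wallXyz), 3)
  }

  atoms <- data.frame(
    eleno = seq_len(nAtoms),
    name = c(rep(c("CA", "C", "O"), n), rep("ZZ", nWall)),
    resno = c(rep(seq_len(n), each = atomsPerRes),
              n + seq_len(nWall)),
    resname = c(rep("GLY", ncAtoms), rep("WAL", nWall)),
    chain = c(rep("N", ncAtoms),
              rep("W", nrow(w$wall)), rep("P", nrow(w$loop23)),
              rep("Q", nrow(w$loop24))),
    element = c(rep(c("C", "C", "O"), n), rep("C", nWall)),
    role = c(rep("NC", ncAtoms),
             rep("rRNA:wall", nrow(w$wall)),
             rep("protein:uL23", nrow(w$loop23)),
             rep("protein:uL24", nrow(w$loop24))),
    stringsAsFactors = FALSE)
  new("StructureEnsemble", atoms = atoms, coords = coords)
}
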