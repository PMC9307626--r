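.checkVolumeTable <- function(table) {
  need <- c("residue", "linker_L", "volume", "volume_sd", "n_scans",
            "concentration", "conc_sd")
  if (!all(need %in% names(table)))
    stop("peak-volume table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$volume < 0)) stop("volumes must be >= 0", call. = FALSE)
  if (anyDuplicated(table[c("residue", "linker_L")]))
    stop("each (residue, linker length) pair must be unique", call. = FALSE)
  invisible(table)
}

#' Relative intensity profile across linker lengths
#'
#' Normalises per-residue cross-peak volumes into a relative intensity
#' profile: per linker length, volumes are scaled by the number of scans
#' and the relative nascent-chain concentration, averaged over the marker
#' residues, and divided by the same quantity at the reference length
#' (I0: the fully unfolded record for the U channel, the fully folded one
#' for the F channel). The sd combines the spectral-noise sd of the
#' volumes and the concentration sd in quadrature (relative errors); the
#' reference point has relative intensity 1 by construction.
#'
#' @param table peak-volume data.frame (see [simulateIntensityProfile()]):
#'   columns `residue`, `linker_L`, `volume`, `volume_sd`, `n_scans`,
#'   `concentration`, `conc_sd`.
#' @param markerResidues residues to average over; all must be present at
#'   the reference length. Lengths at which some markers are missing are
#'   reported from the reduced set and flagged.
#' @param referenceL linker length used as I0.
#' @return data.frame with columns `linker_L`, `intensity`, `sd`,
#'   `nMarkers`, `reducedMarkers`, plus attributes `"channel"` and
#'   `"referenceL"`.
#' @examples
#' tabs <- simulateIntensityProfile(onsetL = 34,
#'   lengths = c(21, 31, 34, 37, 67))
#' relativeProfile(tabs$F, c(674, 695, 738, 743), referenceL = 67)
#' @export
relativeProfile <- function(table, markerResidues, referenceL) {
  .checkVolumeTable(table)
  table <- table[table$residue %in% markerResidues, ]
  if (!referenceL %in% table$linker_L)
    stop("reference length ", referenceL, " is missing from the table",
         call. = FALSE)
  ref <- table[table$linker_L == referenceL, ]
  if (!all(markerResidues %in% ref$residue))
    stop("marker residue(s) ",
         paste(setdiff(markerResidues, ref$residue), collapse = ", "),
         " missing at the reference length", call. = FALSE)
  scaled <- table$volume / (table$n_scans * table$concentration)
  relSd2 <- ifelse(table$volume > 0, (table$volume_sd / table$volume)^2, 0) +
    ifelse(table$concentration > 0,
           (table$conc_sd / table$concentration)^2, 0)
  i0 <- mean(scaled[table$linker_L == referenceL])
  lengths <- sort(unique(table$linker_L))
  out <- do.call(rbind, lapply(lengths, function(L) {
    sel <- table$linker_L == L
    m <- sum(sel)
    val <- mean(scaled[sel]) / i0
    sdv <- val * sqrt(sum(relSd2[sel])) / m
    data.frame(linker_L = L, intensity = val, sd = sdv, nMarkers = m,
               reducedMarkers = m < length(markerResidues))
  }))
  if (any(out$reducedMarkers))
    warning("some lengths are missing markers; reported from reduced sets")
  attr(out, "channel") <- attr(table, "channel")
  attr(out, "referenceL") <- referenceL
  out
}

#' Unweighted moving average
#'
#' Plain mean over each contiguous window; the output has
#' `n - window + 1` points and no padding. This is a display smoother
#' (the four-point moving average drawn through intensity profiles) and
#' never feeds the onset estimator.
#'
#' @param series numeric vector.
#' @param window window length, `1 <= window <= length(series)`.
#' @return numeric vector of length `length(series) - window + 1`.
#' @examples
#' movingAverage(0:5, 4) # 1.5 2.5 3.5
#' @export
movingAverage <- function(series, window = 4L) {
  n <- length(series)
  if (window < 1L || window > n)
    stop("window must be between 1 and the series length", call. = FALSE)
  as.numeric(stats::filter(series, rep(1 / window, window),
                           sides = 1))[window:n]
}

#' Folding onset from a relative intensity profile
#'
#' The smallest linker length at which the profile crosses the threshold,
#' found by linear interpolation between adjacent measured points (in
#' either direction, so rising folded-channel and falling
#' unfolded-channel profiles are both handled). If every point is already
#' beyond the first crossing direction the result is a bound: `"<Lmin"`
#' when the profile starts above the threshold, `">Lmax"` when it never
#' reaches it.
#'
#' @param profile data.frame from [relativeProfile()] (columns `linker_L`,
#'   `intensity`), or any data.frame with those columns.
#' @param threshold crossing level (default 0.5).
#' @return list with `onset` (residues, `NA` for bounds), `bound` (one of
#'   `"none"`, `"belowMin"`, `"aboveMax"`) and `label` (e.g. `"34.0"`,
#'   `"<31"`, `">42"`).
#' @examples
#' prof <- data.frame(linker_L = c(31, 34, 37), intensity = c(0.2, 0.5, 0.9))
#' foldingOnset(prof)$onset # 34
#' @export
foldingOnset <- function(profile, threshold = 0.5) {
  L <- profile$linker_L
  y <- profile$intensity
  ord <- order(L)
  L <- L[ord]; y <- y[ord]
  above <- y >= threshold
  if (all(above))
    return(list(onset = NA_real_, bound = "belowMin",
                label = sprintf("<%g", min(L))))
  if (!any(above))
    return(list(onset = NA_real_, bound = "aboveMax",
                label = sprintf(">%g", max(L))))
  for (i in seq_len(length(L) - 1L)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if ((y0 < threshold && y1 >= threshold) ||
        (y0 >= threshold && y1 < threshold)) {
      onset <- L[i] + (threshold - y0) / (y1 - y0) * (L[i + 1L] - L[i])
      return(list(onset = onset, bound = "none",
                  label = sprintf("%.1f", onset)))
    }
  }
  list(onset = NA_real_, bound = "none", label = NA_character_)
}

#' Fraction full length from an arrest-peptide force assay
#'
#' `f_FL = FL / (FL + A)` from gel densitometry of the full-length (FL)
#' and arrested (A) bands. With several replicates the mean and sd across
#' replicates are reported.
#'
#' @param gel data.frame with columns `FL`, `A` and optionally
#'   `replicate`.
#' @return list with `fFL` (mean over replicates), `sd` (`NA` for a
#'   single replicate) and `perReplicate`.
#' @examples
#' fFL(data.frame(FL = c(2, 3), A = c(6, 5)))
#' @export
fFL <- function(gel) {
  if (any(gel$FL < 0 | gel$A < 0))
    stop("band densities must be >= 0", call. = FALSE)
  if (any(gel$FL + gel$A == 0))
    stop("FL + A must be > 0", call. = FALSE)
  f <- gel$FL / (gel$FL + gel$A)
  list(fFL = mean(f), sd = if (length(f) > 1) sd(f) else NA_real_,
       perReplicate = f)
}
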