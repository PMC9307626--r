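# Frequency-domain lineshape model: narrow U/F Lorentzians, an optional
# broad component, and a complex polynomial baseline on a [-1, 1]-rescaled
# axis. All fitting is joint over the real and imaginary spectral channels,
# which for this model class is likelihood-equivalent to fitting the two
# FID components directly.

.lwBoundsNarrow <- c(1, 2000)      # Hz, log-uniform prior support
.lwBoundsBroad <- c(500, 20000)   # Hz

.rescaleAxis <- function(axis) {
  2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
}

# Parameter bookkeeping shared by fitMap and samplePosterior.
.paramNames <- function(nNarrow, broad, degree) {
  pk <- as.vector(vapply(seq_len(nNarrow), function(k)
    paste0(c("pos", "fwhm", "area", "phase"), k), character(4)))
  if (broad) pk <- c(pk, paste0(c("pos", "fwhm", "area", "phase"), "B"))
  if (degree >= 0)
    pk <- c(pk, paste0("bre", 0:degree), paste0("bim", 0:degree))
  pk
}

#' Evaluate a lineshape model on a ppm axis
#'
#' Each peak contributes the complex Lorentzian
#' `2 a e^{i phi} / (pi w + i 2 pi (nu - nu0))` (`nu` in Hz), scaled so
#' that the integral of the absorptive (real, `phi = 0`) part over
#' frequency equals the area `a`, with FWHM `w` and peak height
#' `2a/(pi w)`. The complex polynomial baseline is evaluated on the axis
#' rescaled to `[-1, 1]` and added to both channels.
#'
#' @param model a [LineshapeModel-class].
#' @param axis numeric ppm axis (uniform).
#' @param sfo transmitter frequency, MHz.
#' @return complex vector of model values.
#' @examples
#' m <- new("LineshapeModel",
#'          peaks = data.frame(position = 0, fwhm = 50, area = 1, phase = 0,
#'                             label = "F"),
#'          broad = NULL, baseline = complex(0))
#' ax <- seq(2, -2, length.out = 512)
#' vals <- modelSpectrum(m, ax, sfo = 470.4)
#' @export
modelSpectrum <- function(model, axis, sfo) {
  stopifnot(is(model, "LineshapeModel"))
  pk <- if (!is.null(model@broad) && nrow(model@broad))
    rbind(model@peaks, model@broad) else model@peaks
  cppModelEval(axis * sfo, .rescaleAxis(axis), sfo,
               as.numeric(pk$position), as.numeric(pk$fwhm),
               as.numeric(pk$area), as.numeric(pk$phase),
               Re(model@baseline), Im(model@baseline))
}

# Simple iterative peak picker for initial values: repeatedly take the
# maximum of the smoothed real part, estimate the width from half-height
# crossings, subtract the implied Lorentzian.
.pickPeaks <- function(axis, re, sfo, n) {
  sm <- stats::filter(re, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  work <- as.numeric(sm)
  out <- data.frame(position = numeric(0), fwhm = numeric(0),
                    area = numeric(0))
  dppm <- abs(stats::median(diff(axis)))
  for (k in seq_len(n)) {
    i <- which.max(work)
    h <- work[i]
    if (h <= 0) h <- max(abs(work)) * 0.1 + 1e-12
    l <- i
    while (l > 1L && work[l - 1L] >= h / 2) l <- l - 1L
    r <- i
    while (r < length(work) && work[r + 1L] >= h / 2) r <- r + 1L
    wHz <- max(r - l + 1L, 3) * dppm * sfo
    wHz <- min(max(wHz, 5), 500)
    out <- rbind(out, data.frame(position = axis[i], fwhm = wHz,
                                 area = abs(h) * pi * wHz / 2))
    lor <- abs(h) / (1 + (2 * (axis - axis[i]) * sfo / wHz)^2)
    work <- work - lor
  }
  out
}

.trapzHz <- function(axis, y, sfo) {
  hz <- axis * sfo
  sum(diff(hz) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Fit a lineshape model by nonlinear least squares
#'
#' Point estimation of the Lorentzian mixture plus baseline by
#' Levenberg-Marquardt least squares on the concatenated (real, imaginary)
#' residual with an analytic Jacobian, weighted by the spectral noise sd.
#' Reports the maximised Gaussian log-likelihood and
#' `BIC = k log(n) - 2 logLik` with `n = 2 *` number of spectral points and
#' `k` the number of free parameters. Restarts from jittered initial
#' values on non-convergence; a result is always returned, carrying the
#' best residual, with `converged` set accordingly. Peaks closer than
#' 1e-3 ppm are flagged as a collision.
#'
#' @param spec a [Spectrum1D-class]; `noiseSd` is used if set, otherwise
#'   estimated by robust MAD of the real channel.
#' @param nPeaks number of narrow state peaks (1-3).
#' @param degree polynomial baseline degree (0-3), or -1 for no baseline.
#' @param broad add a broad background component (FWHM in
#'   `[500, 20000]` Hz)?
#' @param init optional [LineshapeModel-class] with starting values.
#' @param refShifts named numeric `c(U = , F = )` reference shifts in ppm
#'   used to label the state peaks; `NULL` labels the most downfield peak
#'   F and the next U.
#' @param maxRestarts jittered restarts on non-convergence.
#' @return A [FitResult-class] with an empty posterior.
#' @examples
#' truth <- groundTruthSpectrum(0.59, noiseSd = 1e-4)
#' spec <- fourierTransform(simulateFid(truth, seed = 1))
#' fit <- fitMap(spec, nPeaks = 2, degree = 0)
#' @export
fitMap <- function(spec, nPeaks = 2L, degree = 0L, broad = FALSE,
                   init = NULL, refShifts = c(U = -62.4, F = -61.6),
                   maxRestarts = 5L) {
  stopifnot(is(spec, "Spectrum1D"))
  if (!nPeaks %in% 1:3) stop("nPeaks must be 1, 2 or 3", call. = FALSE)
  if (degree > 3) stop("baseline degree is capped at 3", call. = FALSE)
  axis <- spec@axis
  yre <- Re(spec@values)
  yim <- Im(spec@values)
  sigma <- spec@noiseSd
  if (is.na(sigma)) sigma <- mad(yre, center = median(yre))
  if (!is.finite(sigma) || sigma <= 0) sigma <- sd(yre) + 1e-12
  xs <- .rescaleAxis(axis)
  nbase <- if (degree >= 0) degree + 1L else 0L
  npk <- nPeaks + as.integer(broad)

  theta0 <- if (!is.null(init)) {
    pk <- init@peaks
    th <- as.vector(t(cbind(pk$position, log(pk$fwhm), pk$area, pk$phase)))
    if (broad) {
      b <- if (!is.null(init@broad) && nrow(init@broad)) init@broad else
        data.frame(position = mean(range(axis)), fwhm = 1500,
                   area = 0.05 * abs(.trapzHz(axis, yre, spec@sfo)),
                   phase = 0)
      th <- c(th, b$position[1], log(b$fwhm[1]), b$area[1], b$phase[1])
    }
    base0 <- rep(0, 2 * nbase)
    if (length(init@baseline)) {
      nb <- min(length(init@baseline), nbase)
      base0[seq_len(nb)] <- Re(init@baseline)[seq_len(nb)]
      base0[nbase + seq_len(nb)] <- Im(init@baseline)[seq_len(nb)]
    }
    c(th, base0)
  } else {
    picked <- .pickPeaks(axis, yre, spec@sfo, nPeaks)
    th <- as.vector(t(cbind(picked$position, log(picked$fwhm), picked$area,
                            rep(0, nPeaks))))
    if (broad)
      th <- c(th, mean(range(axis)), log(1500),
              0.1 * abs(.trapzHz(axis, yre, spec@sfo)) + sigma, 0)
    c(th, rep(0, 2 * nbase))
  }

  runFit <- function(th) {
    minpack.lm::nls.lm(
      par = th,
      fn = function(p) cppResidJac(p, yre, yim, axis * spec@sfo, xs,
                                   spec@sfo, npk, nbase, sigma,
                                   FALSE)$residuals,
      jac = function(p) cppResidJac(p, yre, yim, axis * spec@sfo, xs,
                                    spec@sfo, npk, nbase, sigma,
                                    TRUE)$jacobian,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14, gtol = 0))
  }
  best <- runFit(theta0)
  attempts <- 0L
  while (!(best$info %in% 1:4) && attempts < maxRestarts) {
    attempts <- attempts + 1L
    jit <- theta0 + rnorm(length(theta0), sd = 0.05 * (abs(theta0) + 0.01))
    cand <- runFit(jit)
    if (cand$deviance < best$deviance) best <- cand
  }
  # refinement: a weak peak initialised on a noise feature can trap the
  # optimiser; re-seed the smallest-area peak at the largest residual and
  # keep the refit when it improves the deviance
  if (nPeaks >= 2) {
    for (round in 1:2) {
      mo <- cppResidJac(best$par, yre, yim, axis * spec@sfo, xs, spec@sfo,
                        npk, nbase, sigma, FALSE)
      rre <- yre - mo$mre
      sm <- stats::filter(rre, rep(1 / 5, 5), sides = 2)
      sm[is.na(sm)] <- 0
      iMax <- which.max(abs(sm))
      weak <- which.min(abs(best$par[4 * seq_len(nPeaks) - 1]))
      th2 <- best$par
      th2[4 * weak - 3] <- axis[iMax]
      th2[4 * weak - 2] <- log(80)
      th2[4 * weak - 1] <- abs(sm[iMax]) * pi * 80 / 2
      th2[4 * weak] <- 0
      cand <- suppressWarnings(runFit(th2))
      if (is.finite(cand$deviance) &&
          cand$deviance < best$deviance - 1e-9) best <- cand else break
    }
  }
  converged <- best$info %in% 1:4

  th <- best$par
  flags <- character()
  # normalise: areas >= 0 (fold sign into phase), phases wrapped
  for (k in seq_len(npk)) {
    a <- th[4 * k - 1]
    if (a < 0) {
      th[4 * k - 1] <- -a
      th[4 * k] <- th[4 * k] + pi
    }
    th[4 * k] <- wrapPhase(th[4 * k])
  }
  posAll <- th[4 * seq_len(nPeaks) - 3]
  if (nPeaks >= 2 && min(dist(posAll)) < 1e-3)
    flags <- c(flags, "peak-collision: state peak positions within 1e-3 ppm")

  narrow <- data.frame(position = th[4 * seq_len(nPeaks) - 3],
                       fwhm = exp(th[4 * seq_len(nPeaks) - 2]),
                       area = th[4 * seq_len(nPeaks) - 1],
                       phase = th[4 * seq_len(nPeaks)],
                       label = NA_character_, stringsAsFactors = FALSE)
  narrow$label <- .labelPeaks(narrow$position, refShifts)
  broadDf <- NULL
  if (broad) {
    i <- 4 * npk - 3
    broadDf <- data.frame(position = th[i], fwhm = exp(th[i + 1]),
                          area = th[i + 2], phase = th[i + 3],
                          label = "broad", stringsAsFactors = FALSE)
  }
  baseline <- if (nbase > 0)
    complex(real = th[4 * npk + seq_len(nbase)],
            imaginary = th[4 * npk + nbase + seq_len(nbase)]) else complex(0)
  model <- new("LineshapeModel", peaks = narrow, broad = broadDf,
               baseline = baseline)

  nTot <- 2L * length(yre)
  logLik <- -nTot / 2 * log(2 * pi * sigma^2) - best$deviance / 2
  k <- length(th)
  fit <- new("FitResult", model = model,
             posterior = matrix(numeric(0), 0, k,
                                dimnames = list(NULL,
                                  .paramNames(nPeaks, broad, degree))),
             chainId = integer(0), logLik = logLik,
             bic = k * log(nTot) - 2 * logLik, rhat = numeric(0),
             noiseSd = sigma, nPoints = length(yre), converged = converged,
             flags = flags)
  fit
}

# Assign U/F labels by proximity to reference shifts; ties and missing
# references fall back to: most downfield (highest ppm) peak = F.
.labelPeaks <- function(positions, refShifts) {
  n <- length(positions)
  labels <- rep(NA_character_, n)
  if (!is.null(refShifts) && all(c("U", "F") %in% names(refShifts)) && n >= 2) {
    dU <- abs(positions - refShifts[["U"]])
    dF <- abs(positions - refShifts[["F"]])
    iF <- which.min(dF)
    iU <- which.min(dU)
    if (iF == iU) { # tie: downfield = F
      iF <- which.max(positions)
      iU <- which.min(positions)
    }
    labels[iF] <- "F"
    labels[iU] <- "U"
    extra <- setdiff(seq_len(n), c(iF, iU))
    if (length(extra)) labels[extra] <- sprintf("peak%d", extra)
  } else if (n >= 2) {
    ord <- order(positions, decreasing = TRUE)
    labels[ord[1]] <- "F"
    labels[ord[2]] <- "U"
    if (n > 2) labels[ord[-(1:2)]] <- sprintf("peak%d", ord[-(1:2)])
  } else {
    labels <- "single"
  }
  labels
}

#' Select the lineshape model by BIC
#'
#' Fits every candidate `(nPeaks, degree, broad)` combination with
#' [fitMap()] and returns the fit with the smallest BIC; ties are broken
#' toward fewer parameters, and candidates are ordered internally so the
#' selection does not depend on the order of the candidate list.
#'
#' @inheritParams fitMap
#' @param candidates data.frame with columns `nPeaks`, `degree`, `broad`.
#' @return the winning [FitResult-class]; its `flags` carry the BIC table
#'   as an attribute `"bicTable"` on the result.
#' @examples
#' spec <- fourierTransform(simulateFid(groundTruthSpectrum(0.59,
#'   noiseSd = 2e-5), seed = 1))
#' sel <- selectModel(spec)
#' nrow(peakTable(sel))
#' @export
selectModel <- function(spec,
                        candidates = expand.grid(nPeaks = 1:2,
                                                 degree = 0:1,
                                                 broad = FALSE),
                        refShifts = c(U = -62.4, F = -61.6)) {
  if (!nrow(candidates)) stop("candidates must be non-empty", call. = FALSE)
  k <- 4 * (candidates$nPeaks + as.integer(candidates$broad)) +
    2 * (candidates$degree + 1)
  ord <- order(k, candidates$nPeaks, candidates$degree,
               as.integer(candidates$broad))
  candidates <- candidates[ord, , drop = FALSE]
  fits <- vector("list", nrow(candidates))
  errs <- character()
  for (i in seq_len(nrow(candidates))) {
    fits[[i]] <- tryCatch(
      fitMap(spec, nPeaks = candidates$nPeaks[i],
             degree = candidates$degree[i], broad = candidates$broad[i],
             refShifts = refShifts),
      error = function(e) conditionMessage(e))
    if (is.character(fits[[i]])) {
      errs <- c(errs, fits[[i]])
      fits[i] <- list(NULL)
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all candidate fits failed: ", paste(unique(errs), collapse = "; "),
         call. = FALSE)
  bics <- vapply(fits[ok], function(f) f@bic, numeric(1))
  win <- fits[ok][[which.min(bics)]]
  tab <- cbind(candidates[ok, , drop = FALSE], bic = bics)
  attr(win, "bicTable") <- tab[order(tab$bic), ]
  win
}

#' State populations from a lineshape fit
#'
#' `pF = area_F / (area_F + area_U)`. The broad component and the baseline
#' never enter the sum. With posterior samples present, `pF` is evaluated
#' per draw; the point estimate is the posterior mean and `sdPf` the
#' posterior sd. Without samples the MAP areas are used and `sdPf` is `NA`.
#'
#' @param fit a [FitResult-class] whose model has peaks labeled `"U"` and
#'   `"F"`.
#' @return A [StatePopulations-class].
#' @examples
#' spec <- fourierTransform(simulateFid(groundTruthSpectrum(0.59,
#'   noiseSd = 2e-5), seed = 1))
#' populationsFromFit(fitMap(spec))
#' @export
populationsFromFit <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  pk <- fit@model@peaks
  iF <- which(pk$label == "F")
  iU <- which(pk$label == "U")
  if (length(iF) != 1L || length(iU) != 1L)
    stop("population undefined: fit needs exactly one U and one F state ",
         "peak; for spectra with no detectable F state use detectionBound()",
         call. = FALSE)
  if (nrow(fit@posterior)) {
    aF <- fit@posterior[, paste0("area", iF)]
    aU <- fit@posterior[, paste0("area", iU)]
    draws <- aF / (aF + aU)
    statePopulations(mean(draws), sdPf = sd(draws), source = "posterior",
                     draws = draws)
  } else {
    statePopulations(pk$area[iF] / (pk$area[iF] + pk$area[iU]),
                     source = "map")
  }
}
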