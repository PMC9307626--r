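#' @describeIn nPoints-methods number of complex time-domain points.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @name nPoints-methods
#' @title Number of points in an NMR record
#' @param x a [Fid-class] or [Spectrum1D-class].
#' @return integer point count.
NULL

#' @rdname nPoints-methods
#' @export
setMethod("nPoints", "Fid", function(x) length(x@points))

#' @rdname nPoints-methods
#' @export
setMethod("nPoints", "Spectrum1D", function(x) length(x@values))

#' Spectral values and axis accessors
#'
#' @param x a [Spectrum1D-class].
#' @return `specValues()` returns the complex values, `specAxis()` the ppm
#'   axis, `noiseSd()` the stored noise estimate (`NA` if unset).
#' @export
specValues <- function(x) x@values

#' @rdname specValues
#' @export
specAxis <- function(x) x@axis

#' @rdname specValues
#' @export
noiseSd <- function(x) x@noiseSd

#' Peak table and population accessors
#'
#' @param x a [LineshapeModel-class], [FitResult-class] or
#'   [StatePopulations-class].
#' @return `peakTable()` returns the narrow-peak data.frame;
#'   `broadComponent()` the broad-peak row or `NULL`; `foldedFraction()` and
#'   `unfoldedFraction()` the fractional populations; `bic()` the Bayesian
#'   information criterion of a fit; `posteriorDraws()` the posterior sample
#'   matrix.
#' @export
peakTable <- function(x) {
  if (is(x, "FitResult")) x@model@peaks else x@peaks
}

#' @rdname peakTable
#' @export
broadComponent <- function(x) {
  if (is(x, "FitResult")) x@model@broad else x@broad
}

#' @rdname peakTable
#' @export
foldedFraction <- function(x) x@pF

#' @rdname peakTable
#' @export
unfoldedFraction <- function(x) x@pU

#' @rdname peakTable
#' @export
bic <- function(x) x@bic

#' @rdname peakTable
#' @export
posteriorDraws <- function(x) x@posterior

#' Ensemble accessors
#'
#' @param x a [StructureEnsemble-class].
#' @return `nFrames()` returns the frame count; `atomTable()` the atom
#'   roster; `frameCoords()` the `nAtoms x 3` coordinate matrix of frame `i`.
#' @param i frame index.
#' @export
nFrames <- function(x) dim(x@coords)[3]

#' @rdname nFrames
#' @export
atomTable <- function(x) x@atoms

#' @rdname nFrames
#' @export
frameCoords <- function(x, i = 1L) x@coords[, , i, drop = TRUE]

setMethod("show", "Fid", function(object) {
  cat(sprintf("Fid: %d complex points, dwell %.3g s (aq %.3g s), %s at %.4g MHz, %d scan(s)\n",
              length(object@points), object@dwell,
              length(object@points) * object@dwell, object@nucleus,
              object@sfo, object@nScans))
})

setMethod("show", "Spectrum1D", function(object) {
  cat(sprintf("Spectrum1D: %d points, %.4g .. %.4g ppm at %.4g MHz, noise sd %s\n",
              length(object@values), object@axis[1],
              object@axis[length(object@axis)], object@sfo,
              ifelse(is.na(object@noiseSd), "unset",
                     formatC(object@noiseSd, digits = 3))))
})

setMethod("show", "LineshapeModel", function(object) {
  cat(sprintf("LineshapeModel: %d peak(s)%s, baseline degree %s\n",
              nrow(object@peaks),
              if (!is.null(object@broad) && nrow(object@broad)) " + broad" else "",
              if (length(object@baseline)) length(object@baseline) - 1L else "none"))
  if (nrow(object@peaks)) print(object@peaks, digits = 4)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: logLik %.2f, BIC %.2f, %s, %d posterior draw(s)\n",
              object@logLik, object@bic,
              if (object@converged) "converged" else "NOT converged",
              nrow(object@posterior)))
  show(object@model)
  if (length(object@rhat))
    cat(sprintf("max split-Rhat: %.4f\n", max(object@rhat)))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "StatePopulations", function(object) {
  cat(sprintf("StatePopulations: pF %s %.4f%s, pU %.4f (source: %s)\n",
              if (object@bounded) "<=" else "=", object@pF,
              if (is.na(object@sdPf)) "" else sprintf(" +/- %.4f", object@sdPf),
              object@pU, object@source))
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d atoms, %d frame(s), roles: %s\n",
              nrow(object@atoms), dim(object@coords)[3],
              paste(unique(object@atoms$role), collapse = ", ")))
})
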