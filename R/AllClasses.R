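setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Acquisition parameters for a 1D NMR experiment
#'
#' Defines the sampling of the free induction decay: number of complex
#' points, dwell time, transmitter frequency and carrier position. The
#' spectral width in Hz is `1/dwell` and the acquisition time is
#' `nPoints * dwell`.
#'
#' @slot nPoints integer, number of complex time-domain points (>= 8).
#' @slot dwell numeric, dwell time in seconds (> 0).
#' @slot sfo numeric, transmitter frequency in MHz (> 0).
#' @slot carrier numeric, carrier position in ppm.
#' @export
setClass("AcquisitionParams",
  representation(nPoints = "integer", dwell = "numeric", sfo = "numeric",
                 carrier = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nPoints) != 1L || is.na(object@nPoints) ||
        object@nPoints < 8L)
      msg <- c(msg, "nPoints must be a single integer >= 8")
    if (length(object@dwell) != 1L || !is.finite(object@dwell) ||
        object@dwell <= 0)
      msg <- c(msg, "dwell must be a single positive number")
    if (length(object@sfo) != 1L || !is.finite(object@sfo) || object@sfo <= 0)
      msg <- c(msg, "sfo must be a single positive number (MHz)")
    if (length(object@carrier) != 1L || !is.finite(object@carrier))
      msg <- c(msg, "carrier must be a single finite number (ppm)")
    if (length(msg)) msg else TRUE
  })

#' Construct acquisition parameters
#'
#' Defaults follow a 1D 19F experiment on a 500 MHz (1H) instrument:
#' a 470.4 MHz 19F transmitter (0.9407 x 500.13 MHz) and a 350 ms
#' acquisition time split over 4096 complex points.
#'
#' @param nPoints number of complex points.
#' @param dwell dwell time in seconds; the default gives a 350 ms
#'   acquisition time at `nPoints` points.
#' @param sfo transmitter frequency in MHz.
#' @param carrier carrier position in ppm.
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acq <- acquisitionParams()
#' acq@nPoints * acq@dwell # 0.35 s acquisition time
#' @export
acquisitionParams <- function(nPoints = 4096L, dwell = 0.35 / nPoints,
                              sfo = 470.4, carrier = -62) {
  if (length(nPoints) != 1L || is.na(nPoints) || nPoints <= 0 ||
      length(dwell) != 1L || !is.finite(dwell) || dwell <= 0)
    stop("invalid acquisition: nPoints and dwell must be positive",
         call. = FALSE)
  new("AcquisitionParams", nPoints = as.integer(nPoints), dwell = dwell,
      sfo = sfo, carrier = carrier)
}

#' Complex free induction decay
#'
#' A 1D complex time-domain NMR record with its axis metadata.
#'
#' @slot points complex vector of time-domain samples (>= 8).
#' @slot dwell numeric, dwell time in seconds (> 0).
#' @slot sfo numeric, transmitter frequency in MHz.
#' @slot carrier numeric, carrier position in ppm.
#' @slot nucleus character, observed nucleus label (e.g. "19F").
#' @slot nScans integer, number of accumulated scans (>= 1).
#' @export
setClass("Fid",
  representation(points = "complex", dwell = "numeric", sfo = "numeric",
                 carrier = "numeric", nucleus = "character",
                 nScans = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@points) < 8L) msg <- c(msg, "need at least 8 points")
    if (object@dwell <= 0) msg <- c(msg, "dwell must be > 0")
    if (object@nScans < 1L) msg <- c(msg, "nScans must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' One-dimensional complex spectrum
#'
#' Frequency-domain record on a uniform ppm axis. By NMR convention the
#' axis is stored descending (downfield on the left).
#'
#' @slot values complex spectral values.
#' @slot axis numeric ppm axis, strictly monotone, same length as `values`.
#' @slot sfo numeric, transmitter frequency in MHz.
#' @slot noiseSd numeric, optional noise standard deviation (a.u.); `NA`
#'   when not yet estimated.
#' @export
setClass("Spectrum1D",
  representation(values = "complex", axis = "numeric", sfo = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) != length(object@axis))
      msg <- c(msg, "values and axis must have the same length")
    if (length(object@axis) >= 2L) {
      d <- diff(object@axis)
      if (!(all(d > 0) || all(d < 0)))
        msg <- c(msg, "axis must be strictly monotone")
    }
    if (length(msg)) msg else TRUE
  })

#' Ground truth for a synthetic 19F spectrum
#'
#' Describes the resonances used to simulate a two-state nascent-chain
#' spectrum: narrow unfolded (U) and folded (F) peaks, an optional broad
#' component, and the time-domain noise level.
#'
#' @slot peaks data.frame with columns `position` (ppm), `fwhm` (Hz),
#'   `area` (a.u.), `phase` (rad) and `label` ("U"/"F" or other).
#' @slot broad data.frame with the same columns for the broad component,
#'   or `NULL`.
#' @slot foldedFraction numeric in `[0, 1]`; must equal
#'   area(F)/(area(F)+area(U)) of `peaks`.
#' @slot noiseSd numeric, standard deviation of the complex Gaussian noise
#'   per time-domain point (real and imaginary channels each).
#' @export
setClass("GroundTruthSpectrum",
  representation(peaks = "data.frame", broad = "data.frameOrNULL",
                 foldedFraction = "numeric", noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("position", "fwhm", "area", "phase", "label")
    if (!all(need %in% names(object@peaks)))
      msg <- c(msg, "peaks needs columns position, fwhm, area, phase, label")
    else {
      if (any(object@peaks$fwhm <= 0)) msg <- c(msg, "linewidths must be > 0")
      if (any(object@peaks$area < 0)) msg <- c(msg, "areas must be >= 0")
      aF <- sum(object@peaks$area[object@peaks$label == "F"])
      aU <- sum(object@peaks$area[object@peaks$label == "U"])
      if (aF + aU > 0 &&
          abs(object@foldedFraction - aF / (aF + aU)) > 1e-9)
        msg <- c(msg, "foldedFraction must equal area(F)/(area(F)+area(U))")
    }
    if (!is.null(object@broad) && nrow(object@broad) &&
        any(object@broad$fwhm < 500))
      msg <- c(msg, "broad component must have fwhm >= 500 Hz")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Lorentzian mixture plus polynomial baseline
#'
#' The lineshape model fitted to 19F spectra: narrow state peaks (U, F),
#' an optional broad component, and a complex polynomial baseline evaluated
#' on the axis rescaled to `[-1, 1]`. The broad component and the baseline
#' are excluded from population sums.
#'
#' @slot peaks data.frame with columns `position` (ppm), `fwhm` (Hz),
#'   `area`, `phase` (rad) and `label`.
#' @slot broad data.frame (one row, same columns) or `NULL`.
#' @slot baseline complex vector of polynomial coefficients (degree =
#'   `length(baseline) - 1`, at most 3); `complex(0)` for no baseline.
#' @export
setClass("LineshapeModel",
  representation(peaks = "data.frame", broad = "data.frameOrNULL",
                 baseline = "complex"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@peaks) &&
        (any(object@peaks$fwhm <= 0) || any(object@peaks$area < 0)))
      msg <- c(msg, "peaks must have fwhm > 0 and area >= 0")
    if (length(object@baseline) > 4L)
      msg <- c(msg, "baseline degree must be at most 3")
    if (length(msg)) msg else TRUE
  })

#' Result of a lineshape fit
#'
#' Point estimate, optional posterior samples, and fit diagnostics for a
#' [LineshapeModel-class] fitted to a [Spectrum1D-class].
#'
#' @slot model the point-estimate [LineshapeModel-class].
#' @slot posterior numeric matrix of posterior draws (rows = draws, columns
#'   = natural-scale parameters) or a 0-row matrix when no sampling was run.
#' @slot chainId integer vector mapping posterior rows to chains.
#' @slot logLik numeric, maximised log-likelihood under Gaussian noise.
#' @slot bic numeric, `k*log(n) - 2*logLik` with `n = 2 *` number of
#'   spectral points.
#' @slot rhat named numeric vector of split-Rhat statistics (empty before
#'   sampling).
#' @slot noiseSd numeric, the (fixed) noise standard deviation used.
#' @slot nPoints integer, number of spectral points fitted.
#' @slot converged logical.
#' @slot flags character vector of quality warnings (e.g. peak collision).
#' @export
setClass("FitResult",
  representation(model = "LineshapeModel", posterior = "matrix",
                 chainId = "integer", logLik = "numeric", bic = "numeric",
                 rhat = "numeric", noiseSd = "numeric", nPoints = "integer",
                 converged = "logical", flags = "character"))

#' Folded/unfolded state populations
#'
#' Fractional populations of the folded (F) and unfolded (U) nascent-chain
#' states obtained from peak integrals, with uncertainty. `bounded = TRUE`
#' marks a detection-limit result, where `pF` is an upper bound rather than
#' an estimate.
#'
#' @slot pF,pU numeric fractions in `[0, 1]`, summing to 1.
#' @slot sdPf numeric, standard deviation of `pF` (`NA` when unavailable).
#' @slot bounded logical, `TRUE` for detection-limit bounds.
#' @slot source character, identifier of the originating fit.
#' @slot draws numeric vector of posterior draws of `pF` (may be empty).
#' @export
setClass("StatePopulations",
  representation(pF = "numeric", pU = "numeric", sdPf = "numeric",
                 bounded = "logical", source = "character",
                 draws = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(object@pF + object@pU - 1) > 1e-9)
      msg <- c(msg, "pF + pU must equal 1")
    if (object@pF < 0 || object@pF > 1) msg <- c(msg, "pF must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a StatePopulations object directly
#'
#' @param pF folded fraction in `[0, 1]`.
#' @param sdPf standard deviation of `pF` (`NA` if unknown).
#' @param bounded `TRUE` when `pF` is a detection-limit upper bound.
#' @param source identifier string.
#' @param draws optional posterior draws of `pF`.
#' @return A [StatePopulations-class] object.
#' @examples
#' statePopulations(0.59, sdPf = 0.02)
#' @export
statePopulations <- function(pF, sdPf = NA_real_, bounded = FALSE,
                             source = "manual", draws = numeric()) {
  new("StatePopulations", pF = pF, pU = 1 - pF, sdPf = sdPf,
      bounded = bounded, source = source, draws = draws)
}

#' Thermodynamic configuration
#'
#' Gas constant and temperature used for every free-energy conversion.
#' All energy outputs carry the temperature they were computed at, and
#' mixing temperatures in comparisons is an error.
#'
#' @slot gasConstant numeric, kcal/(mol K).
#' @slot temperature numeric, K (> 0).
#' @export
setClass("ThermoConfig",
  representation(gasConstant = "numeric", temperature = "numeric"),
  validity = function(object) {
    if (object@temperature <= 0) "temperature must be > 0" else TRUE
  })

#' Construct a thermodynamic configuration
#'
#' The default temperature is 298.15 K (25 C, the temperature at which the
#' 19F spectra are recorded); 15N-derived quantities may use 283.15 K.
#'
#' @param temperature temperature in K.
#' @param gasConstant gas constant in kcal/(mol K).
#' @return A [ThermoConfig-class] object.
#' @examples
#' thermoConfig()@temperature
#' @export
thermoConfig <- function(temperature = 298.15, gasConstant = 1.9872e-3) {
  new("ThermoConfig", gasConstant = gasConstant, temperature = temperature)
}

#' Multi-frame coordinate ensemble
#'
#' Cartesian coordinates of a nascent chain plus fixed ribosomal wall over
#' one or more frames, with a constant atom roster. Chain roles classify
#' each atom as nascent chain (`"NC"`) or a ribosomal component (e.g.
#' `"protein:uL23"`, `"rRNA:H24"`).
#'
#' @slot atoms data.frame with columns `eleno`, `name`, `resno`, `resname`,
#'   `chain`, `element`, `role`.
#' @slot coords numeric array of dimension `c(nAtoms, 3, nFrames)`, Angstrom.
#' @export
setClass("StructureEnsemble",
  representation(atoms = "data.frame", coords = "array"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
      msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
    else if (d[1] != nrow(object@atoms))
      msg <- c(msg, "coords first dimension must match the atom table")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(msg)) msg else TRUE
  })
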