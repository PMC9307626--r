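.checkTemps <- function(t1, t2) {
  if (abs(t1 - t2) > 1e-9)
    stop("temperature mismatch: energies computed at ", t1, " K and ", t2,
         " K cannot be combined", call. = FALSE)
}

#' Folding free energy from state populations
#'
#' `dG_F-U = -RT log(pF/pU)` at the configured temperature, with the
#' uncertainty propagated from `sdPf` by the selected mode (see
#' [propagateError()]). Detection-limit populations (`bounded = TRUE`)
#' yield a lower bound (`direction = ">="`), since a smaller folded
#' fraction can only increase the free energy.
#'
#' @param pop a [StatePopulations-class].
#' @param cfg a [ThermoConfig-class].
#' @param variant,linkerL labels recorded in the output.
#' @param mode error-propagation mode, `"delta"` or `"monte_carlo"`.
#' @param nMc,seed Monte Carlo settings for `mode = "monte_carlo"`.
#' @return one-row data.frame with columns `variant`, `linker_L`, `dg`
#'   (kcal/mol), `sd`, `bounded`, `direction`, `temperature`.
#' @examples
#' deltaGFolding(statePopulations(0.59, 0.02), variant = "WT", linkerL = 34)
#' @export
deltaGFolding <- function(pop, cfg = thermoConfig(), variant = "unknown",
                          linkerL = NA_integer_, mode = c("delta",
                                                          "monte_carlo"),
                          nMc = 10000L, seed = 1L) {
  stopifnot(is(pop, "StatePopulations"), is(cfg, "ThermoConfig"))
  mode <- match.arg(mode)
  if (!pop@bounded && (pop@pF <= 0 || pop@pF >= 1))
    stop("infinite energy: pF is exactly ", pop@pF,
         "; use detectionBound() to derive a population bound first",
         call. = FALSE)
  rt <- cfg@gasConstant * cfg@temperature
  dg <- -rt * log(pop@pF / pop@pU)
  sdv <- if (pop@bounded) NA_real_ else
    propagateError(pop, cfg, mode = mode, nMc = nMc, seed = seed)
  data.frame(variant = variant, linker_L = linkerL, dg = dg, sd = sdv,
             bounded = pop@bounded,
             direction = if (pop@bounded) ">=" else "==",
             temperature = cfg@temperature, stringsAsFactors = FALSE)
}

#' Propagate population uncertainty into the free energy
#'
#' Delta mode uses the analytic derivative of `-RT log(p/(1-p))`:
#' `sd = RT * sdPf / (pF * (1 - pF))`. Monte Carlo mode draws `pF` from a
#' normal truncated to (0, 1) and returns the sd of the resulting free
#' energies; the two agree within ~10% for `sdPf <= 0.1` and
#' `0.2 <= pF <= 0.8`.
#'
#' @inheritParams deltaGFolding
#' @return numeric sd in kcal/mol.
#' @examples
#' propagateError(statePopulations(0.5, 0.05)) # 0.1185 kcal/mol
#' @export
propagateError <- function(pop, cfg = thermoConfig(),
                           mode = c("delta", "monte_carlo"), nMc = 10000L,
                           seed = 1L) {
  stopifnot(is(pop, "StatePopulations"))
  mode <- match.arg(mode)
  if (is.na(pop@sdPf)) return(NA_real_)
  if (pop@sdPf == 0) return(0)
  rt <- cfg@gasConstant * cfg@temperature
  if (mode == "delta") {
    rt * pop@sdPf / (pop@pF * (1 - pop@pF))
  } else {
    set.seed(seed)
    draws <- rnorm(ceiling(nMc * 1.5), mean = pop@pF, sd = pop@sdPf)
    draws <- draws[draws > 0 & draws < 1][seq_len(nMc)]
    draws <- draws[!is.na(draws)]
    sd(-rt * log(draws / (1 - draws)))
  }
}

#' Free-energy difference between a variant and the wild type
#'
#' `ddG = dG(variant) - dG(WT)`, with `sd = sqrt(sd1^2 + sd2^2)`. Both
#' energies must refer to the same linker length and temperature. A
#' detection-limit bound on either side propagates as an inequality on
#' the difference.
#'
#' @param variant,wt one-row data.frames from [deltaGFolding()].
#' @return one-row data.frame with `variant`, `linker_L`, `ddg`, `sd`,
#'   `bounded`, `direction`, `temperature`.
#' @examples
#' wt <- deltaGFolding(statePopulations(0.08, 0.07), variant = "WT",
#'                     linkerL = 31)
#' mu <- deltaGFolding(statePopulations(0.42, 0.07), variant = "23dL24dL",
#'                     linkerL = 31)
#' ddgFolding(mu, wt) # about -1.26 kcal/mol
#' @export
ddgFolding <- function(variant, wt) {
  lSame <- (is.na(variant$linker_L) && is.na(wt$linker_L)) ||
    (!is.na(variant$linker_L) && !is.na(wt$linker_L) &&
       variant$linker_L == wt$linker_L)
  if (!lSame)
    stop("comparison error: linker lengths differ (", variant$linker_L,
         " vs ", wt$linker_L, ")", call. = FALSE)
  .checkTemps(variant$temperature, wt$temperature)
  bounded <- variant$bounded | wt$bounded
  direction <- if (!bounded) "==" else if (variant$bounded) ">=" else "<="
  data.frame(variant = variant$variant, linker_L = variant$linker_L,
             ddg = variant$dg - wt$dg,
             sd = sqrt(sum(c(variant$sd, wt$sd)^2)),
             bounded = bounded, direction = direction,
             temperature = variant$temperature, stringsAsFactors = FALSE)
}

#' Detection-limit bound on an undetected folded population
#'
#' When no F-state peak is observed, the largest population that could
#' have escaped detection is estimated from the spectral noise: a peak of
#' height `kSigma * noise` with the U-state linewidth has area
#' `kSigma * noise * pi * fwhm_U / 2`; the bound is that area divided by
#' the total (U + hidden F) area, capped at `cap` (default 1%).
#'
#' @param noiseSd spectral noise sd (a.u.).
#' @param uPeak one-row data.frame or list with `fwhm` (Hz) and `area` of
#'   the fitted U peak.
#' @param kSigma detection threshold in noise sd units.
#' @param cap maximum population bound (the 1% convention).
#' @return a bounded [StatePopulations-class] whose `pF` is the upper
#'   bound.
#' @examples
#' detectionBound(1e-4, list(fwhm = 70, area = 1))
#' @export
detectionBound <- function(noiseSd, uPeak, kSigma = 3, cap = 0.01) {
  if (is.null(uPeak$area) || uPeak$area[1] <= 0)
    stop("detection bound undefined: U-peak area must be > 0", call. = FALSE)
  if (noiseSd <= 0) {
    warning("zero spectral noise: returning the population cap")
    return(statePopulations(cap, bounded = TRUE, source = "detection-bound"))
  }
  aMax <- kSigma * noiseSd * pi * uPeak$fwhm[1] / 2
  bound <- min(cap, aMax / (aMax + uPeak$area[1]))
  statePopulations(bound, bounded = TRUE, source = "detection-bound")
}

#' Attenuation of folding-energy changes with linker length
#'
#' For each variant present at both linker lengths, computes the
#' percentage decrease in the magnitude of the folding-energy change,
#' `100 * (|ddG_L31| - |ddG_L34|) / |ddG_L31|`, and returns the mean and
#' sd across variants. Detection-limit-derived values are included by
#' default (they enter as their capped-population estimates) and can be
#' excluded with `includeBounded = FALSE`; they never enter silently.
#'
#' @param ddgShort data.frame of [ddgFolding()] rows at the shorter linker.
#' @param ddgLong data.frame of rows at the longer linker.
#' @param includeBounded include variants whose ddG at either length is a
#'   detection-limit bound?
#' @return list with `mean` and `sd` (percent; `sd` is `NA` for a single
#'   variant), and `perVariant`, the per-variant table.
#' @export
lengthAttenuation <- function(ddgShort, ddgLong, includeBounded = TRUE) {
  common <- intersect(ddgShort$variant, ddgLong$variant)
  if (!length(common))
    stop("no variants present at both linker lengths", call. = FALSE)
  a <- ddgShort[match(common, ddgShort$variant), ]
  b <- ddgLong[match(common, ddgLong$variant), ]
  .checkTemps(a$temperature[1], b$temperature[1])
  keep <- if (includeBounded) rep(TRUE, length(common)) else
    !(a$bounded | b$bounded)
  if (!any(keep))
    stop("no unbounded variant pairs remain", call. = FALSE)
  a <- a[keep, ]; b <- b[keep, ]
  pct <- 100 * (abs(a$ddg) - abs(b$ddg)) / abs(a$ddg)
  list(mean = mean(pct), sd = if (length(pct) > 1) sd(pct) else NA_real_,
       perVariant = data.frame(variant = a$variant, pct = pct,
                               bounded = a$bounded | b$bounded,
                               stringsAsFactors = FALSE))
}

#' Bound/unbound populations from a chemical-shift perturbation
#'
#' In fast exchange the observed shift is the population-weighted average
#' of the bound and unbound reference shifts, so
#' `p_b = (delta_obs - delta_ub) / (delta_b - delta_ub)`. Observations
#' slightly outside the reference interval are clamped to `[0, 1]` with a
#' warning. The sd follows by the delta method, `sd_obs / |delta_b -
#' delta_ub|`.
#'
#' @param obs data.frame with columns `delta_obs`, `delta_unbound`,
#'   `delta_bound`, `sd_obs` and optionally `variant` (e.g. from
#'   [simulateCspSeries()]).
#' @return data.frame with columns `variant`, `p_b`, `p_ub`, `sd_pb`.
#' @examples
#' cspPopulation(data.frame(variant = "WT", delta_obs = 8.45,
#'   delta_unbound = 8.40, delta_bound = 8.50, sd_obs = 0.002))
#' @export
cspPopulation <- function(obs) {
  if (any(obs$delta_bound == obs$delta_unbound))
    stop("reference shifts are equal; bound fraction undefined",
         call. = FALSE)
  pb <- (obs$delta_obs - obs$delta_unbound) /
    (obs$delta_bound - obs$delta_unbound)
  if (any(pb < 0 | pb > 1)) {
    warning("observed shift outside the reference interval; clamping")
    pb <- pmin(pmax(pb, 0), 1)
  }
  data.frame(variant = if (is.null(obs$variant))
               sprintf("obs%02d", seq_along(pb)) else obs$variant,
             p_b = pb, p_ub = 1 - pb,
             sd_pb = obs$sd_obs / abs(obs$delta_bound - obs$delta_unbound),
             stringsAsFactors = FALSE)
}

#' Change in binding free energy between a variant and the wild type
#'
#' `dG_bind = -RT log(p_b / p_ub)` for each side, and
#' `ddG_bind = dG_bind(variant) - dG_bind(WT)`; weaker binding of the
#' nascent chain on the variant ribosome therefore gives a positive
#' `ddG_bind`. Uncertainties are propagated by the delta method from the
#' population sds and combined in quadrature.
#'
#' @param variant,wt one-row data.frames from [cspPopulation()].
#' @param cfg a [ThermoConfig-class].
#' @return one-row data.frame with `variant`, `ddg_bind` (kcal/mol), `sd`,
#'   `temperature`.
#' @examples
#' wt <- data.frame(variant = "WT", p_b = 0.8, p_ub = 0.2, sd_pb = 0.01)
#' mu <- data.frame(variant = "23dL", p_b = 0.6, p_ub = 0.4, sd_pb = 0.01)
#' ddgBinding(mu, wt)
#' @export
ddgBinding <- function(variant, wt, cfg = thermoConfig()) {
  stopifnot(is(cfg, "ThermoConfig"))
  for (x in list(variant, wt))
    if (x$p_b[1] <= 0 || x$p_b[1] >= 1)
      stop("infinite energy: bound population must lie strictly inside ",
           "(0, 1)", call. = FALSE)
  rt <- cfg@gasConstant * cfg@temperature
  dgv <- -rt * log(variant$p_b[1] / variant$p_ub[1])
  dgw <- -rt * log(wt$p_b[1] / wt$p_ub[1])
  sdv <- rt * variant$sd_pb[1] / (variant$p_b[1] * variant$p_ub[1])
  sdw <- rt * wt$sd_pb[1] / (wt$p_b[1] * wt$p_ub[1])
  data.frame(variant = variant$variant[1], ddg_bind = dgv - dgw,
             sd = sqrt(sdv^2 + sdw^2), temperature = cfg@temperature,
             stringsAsFactors = FALSE)
}

#' Correlation between folding and binding free-energy changes
#'
#' Ordinary least squares of the binding changes on the folding changes
#' over paired variants; returns R^2, the slope and the intercept.
#' Detection-limit (bounded) folding values are dropped with a message by
#' default; set `dropBounded = FALSE` to refuse them with an error
#' instead. At least 3 pairs are required.
#'
#' @param ddgFold numeric vector, or data.frame with `ddg` and optionally
#'   `bounded`.
#' @param ddgBind numeric vector or data.frame with `ddg_bind`, paired
#'   with `ddgFold`.
#' @param dropBounded silently refuse (`FALSE`) or drop with a message
#'   (`TRUE`) bounded folding entries.
#' @return list with `r.squared`, `slope`, `intercept`, `n`.
#' @examples
#' energyCorrelation(c(0, 1, 2), c(0, 1, 0))$r.squared # 0.25
#' @export
energyCorrelation <- function(ddgFold, ddgBind, dropBounded = TRUE) {
  bounded <- if (is.data.frame(ddgFold) && !is.null(ddgFold$bounded))
    ddgFold$bounded else rep(FALSE, NROW(ddgFold))
  x <- if (is.data.frame(ddgFold)) ddgFold$ddg else ddgFold
  y <- if (is.data.frame(ddgBind)) ddgBind$ddg_bind else ddgBind
  if (length(x) != length(y))
    stop("folding and binding changes must be paired", call. = FALSE)
  if (any(bounded)) {
    if (!dropBounded)
      stop("bounded (detection-limit) energies cannot enter the regression",
           call. = FALSE)
    message("dropping ", sum(bounded), " bounded pair(s) from the regression")
    x <- x[!bounded]; y <- y[!bounded]
  }
  if (length(x) < 3)
    stop("need at least 3 unbounded pairs", call. = FALSE)
  fit <- lm(y ~ x)
  list(r.squared = summary(fit)$r.squared, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = length(x))
}
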