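test_that("folding free energy evaluates the two-state formula", {
  expect_equal(deltaGFolding(statePopulations(0.5))$dg, 0)
  # p_f = 0.59 at 298.15 K
  expect_equal(deltaGFolding(statePopulations(0.59))$dg, -0.21566,
               tolerance = 1e-4)
  # p_f at the 1% detection cap
  expect_equal(deltaGFolding(statePopulations(0.01, bounded = TRUE))$dg,
               2.7225, tolerance = 1e-4)
  expect_error(deltaGFolding(statePopulations(1)), "infinite energy")
  expect_error(deltaGFolding(statePopulations(0)), "infinite energy")
  # antisymmetry dG(p) = -dG(1-p)
  for (p in c(0.1, 0.25, 0.41, 0.73, 0.9))
    expect_equal(deltaGFolding(statePopulations(p))$dg,
                 -deltaGFolding(statePopulations(1 - p))$dg,
                 tolerance = 1e-12)
})

test_that("error propagation matches the analytic derivative and Monte Carlo", {
  expect_equal(propagateError(statePopulations(0.5, 0.05)), 0.11850,
               tolerance = 1e-4)
  expect_equal(propagateError(statePopulations(0.3, 0)), 0)
  expect_true(is.na(propagateError(statePopulations(0.3))))
  # first-order validity region (verified by exact large-sample Monte
  # Carlo): within 10% across p in [0.2, 0.8] for sd <= 0.05, and up to
  # sd = 0.1 at mid populations where the logit curvature vanishes
  cases <- rbind(expand.grid(p = c(0.2, 0.5, 0.8), s = c(0.02, 0.05)),
                 data.frame(p = 0.5, s = 0.1))
  for (i in seq_len(nrow(cases))) {
    pop <- statePopulations(cases$p[i], cases$s[i])
    d <- propagateError(pop, mode = "delta")
    m <- propagateError(pop, mode = "monte_carlo", nMc = 50000L, seed = 2)
    expect_lt(abs(d - m) / d, 0.10)
  }
  # outside that region the delta method genuinely underestimates the
  # spread of the heavy-tailed log-odds transform
  popEdge <- statePopulations(0.2, 0.1)
  dE <- propagateError(popEdge, mode = "delta")
  mE <- propagateError(popEdge, mode = "monte_carlo", nMc = 50000L,
                       seed = 2)
  expect_gt(abs(dE - mE) / dE, 0.10)
  # Monte Carlo estimate is converged at the default draw count
  pop <- statePopulations(0.4, 0.06)
  m1 <- propagateError(pop, mode = "monte_carlo", nMc = 10000L, seed = 3)
  m2 <- propagateError(pop, mode = "monte_carlo", nMc = 100000L, seed = 4)
  expect_lt(abs(m1 - m2) / m2, 0.03)
})

test_that("ddG differences telescope and guard their metadata", {
  wt <- deltaGFolding(statePopulations(0.08, 0.07), variant = "WT",
                      linkerL = 31L)
  mu <- deltaGFolding(statePopulations(0.42, 0.07), variant = "23dL24dL",
                      linkerL = 31L)
  dd <- ddgFolding(mu, wt)
  expect_equal(dd$ddg, -1.2557, tolerance = 1e-3)
  expect_equal(dd$sd, sqrt(mu$sd^2 + wt$sd^2))
  expect_equal(ddgFolding(wt, wt)$ddg, 0)

  # chain rule: ddg(A,B) + ddg(B,C) = ddg(A,C) exactly
  a <- deltaGFolding(statePopulations(0.3, 0.02), variant = "A", linkerL = 31L)
  b <- deltaGFolding(statePopulations(0.5, 0.02), variant = "B", linkerL = 31L)
  c3 <- deltaGFolding(statePopulations(0.7, 0.02), variant = "C",
                      linkerL = 31L)
  expect_identical(ddgFolding(a, b)$ddg + ddgFolding(b, c3)$ddg,
                   ddgFolding(a, c3)$ddg)

  other <- deltaGFolding(statePopulations(0.42, 0.07), linkerL = 34L)
  expect_error(ddgFolding(other, wt), "linker lengths differ")
  cold <- deltaGFolding(statePopulations(0.42, 0.07),
                        cfg = thermoConfig(283.15), linkerL = 31L)
  expect_error(ddgFolding(cold, wt), "temperature mismatch")
})

test_that("detection bound converts noise height to a population cap", {
  # very high SNR: the computed bound undercuts the 1% cap
  b <- detectionBound(1e-6, list(fwhm = 70, area = 1))
  expect_true(b@bounded)
  expect_lt(b@pF, 0.01)
  # the analytic height-to-area conversion: area = 3*sigma*pi*w/2
  expect_equal(b@pF, (3e-6 * pi * 70 / 2) / (3e-6 * pi * 70 / 2 + 1))
  # low SNR caps at 1%
  expect_equal(detectionBound(1, list(fwhm = 70, area = 1))@pF, 0.01)
  expect_error(detectionBound(1e-4, list(fwhm = 70, area = 0)), "area")
  expect_warning(bb <- detectionBound(0, list(fwhm = 70, area = 1)),
                 "zero spectral noise")
  expect_equal(bb@pF, 0.01)
  # a bounded population yields a lower-bound free energy
  expect_identical(deltaGFolding(bb)$direction, ">=")
})

test_that("length attenuation summarises paired ddG magnitudes", {
  mk <- function(v, dg, L) data.frame(variant = v, linker_L = L, ddg = dg,
                                      sd = 0.1, bounded = FALSE,
                                      direction = "==", temperature = 298.15)
  short <- mk(c("a", "b", "c"), c(-1, 2, -0.5), 31L)
  long <- mk(c("a", "b", "c"), c(-0.5, 1, -0.25), 34L)
  att <- lengthAttenuation(short, long)
  expect_equal(att$mean, 50)
  expect_equal(att$sd, 0)
  single <- lengthAttenuation(short[1, ], long[1, ])
  expect_true(is.na(single$sd))
  expect_error(lengthAttenuation(short, mk("z", 1, 34L)), "no variants")
})

test_that("CSP populations are the linear shift interpolant", {
  obs <- function(d) data.frame(variant = "x", delta_obs = d,
                                delta_unbound = 8.40, delta_bound = 8.50,
                                sd_obs = 0.004)
  expect_equal(cspPopulation(obs(8.40))$p_b, 0)
  expect_equal(cspPopulation(obs(8.50))$p_b, 1)
  expect_equal(cspPopulation(obs(8.45))$p_b, 0.5)
  expect_equal(cspPopulation(obs(8.45))$sd_pb, 0.04)
  # strictly increasing in the observed shift
  pbs <- vapply(seq(8.41, 8.49, by = 0.01),
                function(d) cspPopulation(obs(d))$p_b, numeric(1))
  expect_true(all(diff(pbs) > 0))
  expect_warning(cspPopulation(obs(8.55)), "clamping")
  bad <- obs(8.45)
  bad$delta_bound <- 8.40
  expect_error(cspPopulation(bad), "equal")
})

test_that("binding ddG is antisymmetric with the stated sign convention", {
  mk <- function(pb) data.frame(variant = "v", p_b = pb, p_ub = 1 - pb,
                                sd_pb = 0.01)
  expect_equal(ddgBinding(mk(0.5), mk(0.5))$ddg_bind, 0)
  # weaker binding on the variant => positive ddG
  expect_gt(ddgBinding(mk(0.3), mk(0.7))$ddg_bind, 0)
  expect_equal(ddgBinding(mk(0.3), mk(0.7))$ddg_bind,
               -ddgBinding(mk(0.7), mk(0.3))$ddg_bind)
  expect_error(ddgBinding(mk(1), mk(0.5)), "infinite energy")
})

test_that("energy correlation reproduces closed-form least squares", {
  expect_equal(suppressWarnings(
    energyCorrelation(c(0, 1, 2), c(1, 3, 5))$r.squared), 1)
  # symmetric tent data: the covariance vanishes, so R^2 is exactly 0
  h <- handOls(c(0, 1, 2), c(0, 1, 0))
  res <- energyCorrelation(c(0, 1, 2), c(0, 1, 0))
  expect_equal(res$r.squared, h$r2)
  expect_equal(res$r.squared, 0)
  expect_equal(res$slope, h$slope)
  h2 <- handOls(c(0, 1, 3), c(0.2, 1.1, 0.4))
  res2 <- energyCorrelation(c(0, 1, 3), c(0.2, 1.1, 0.4))
  expect_equal(res2$r.squared, h2$r2)
  expect_equal(res2$slope, h2$slope)
  expect_equal(res2$intercept, h2$intercept)
  # R^2 invariant to affine rescaling of either axis
  x <- c(0.1, 0.9, 0.4, 0.7)
  y <- c(0.2, 1.1, 0.3, 0.9)
  r0 <- energyCorrelation(x, y)$r.squared
  expect_equal(energyCorrelation(3 * x - 1, y)$r.squared, r0)
  expect_equal(energyCorrelation(x, -2 * y + 5)$r.squared, r0)
  expect_error(energyCorrelation(c(0, 1), c(0, 1)), "at least 3")
  # bounded energies never enter silently
  fold <- data.frame(ddg = c(0, 1, 2, 3), bounded = c(FALSE, FALSE, FALSE,
                                                      TRUE))
  bind <- data.frame(ddg_bind = c(0.1, 1.2, 1.8, 3))
  expect_message(withB <- energyCorrelation(fold, bind), "dropping 1")
  expect_identical(withB$n, 3L)
  expect_error(energyCorrelation(fold, bind, dropBounded = FALSE),
               "cannot enter")
})

test_that("frequency separation converts ppm on a heteronuclear axis", {
  expect_equal(frequencySeparation(0, 500.13), 0)
  expect_equal(frequencySeparation(1, 470.4 / 0.9407, "19F"), 470.4)
  sep <- frequencySeparation(0.8, 500.13, "19F")
  expect_equal(sep, 376.3, tolerance = 1e-3)
  expect_error(frequencySeparation(0.8, 500.13, "31P"), "unknown nucleus")
})
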