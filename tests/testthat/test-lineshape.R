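mkModel <- function(peaks, broad = NULL, baseline = complex(0)) {
  new("LineshapeModel", peaks = peaks, broad = broad, baseline = baseline)
}

test_that("model spectrum has absorptive/dispersive symmetry and unit area", {
  ax <- seq(2, -2, length.out = 4097)  # odd length: the position 0 is on-grid
  # +/- 2 ppm = +/- 940.8 Hz: a 52 FWHM half-window for an 18 Hz line,
  # where the Lorentzian tail truncation is ~0.6%
  m <- mkModel(data.frame(position = 0, fwhm = 18, area = 1.7, phase = 0,
                          label = "F"))
  v <- modelSpectrum(m, ax, sfo = 470.4)
  i0 <- which.max(Re(v))
  expect_equal(ax[i0], 0, tolerance = 2e-3)
  # imaginary part antisymmetric about the position
  expect_equal(Im(v[i0 - 100]), -Im(v[i0 + 100]), tolerance = 1e-3)
  # trapezoidal integral of the real part recovers the area
  hz <- ax * 470.4
  integ <- -sum(diff(hz) * (head(Re(v), -1) + tail(Re(v), -1)) / 2)
  expect_equal(integ, 1.7, tolerance = 0.01)

  # empty model with constant baseline
  m0 <- mkModel(data.frame(position = numeric(0), fwhm = numeric(0),
                           area = numeric(0), phase = numeric(0),
                           label = character(0)),
                baseline = complex(real = 0.25, imaginary = -0.1))
  expect_true(all(modelSpectrum(m0, ax, 470.4) == 0.25 - 0.1i))
})

test_that("noiseless two-peak spectra are recovered to high precision", {
  truth <- data.frame(position = c(-62.4, -61.6), fwhm = c(70, 90),
                      area = c(0.41, 0.59), phase = 0, label = c("U", "F"))
  sp <- freqDomainSpectrum(truth, noiseSd = 1e-9)
  fit <- fitMap(sp, nPeaks = 2, degree = 0)
  pk <- peakTable(fit)
  pk <- pk[order(pk$position), ]
  expect_true(fit@converged)
  expect_equal(pk$position, c(-62.4, -61.6), tolerance = 1e-6)
  expect_equal(pk$fwhm, c(70, 90), tolerance = 1e-6)
  expect_equal(pk$area, c(0.41, 0.59), tolerance = 1e-6)
  expect_equal(pk$phase, c(0, 0), tolerance = 1e-6)
  expect_identical(pk$label[order(pk$position)], c("U", "F"))
})

test_that("residuals of a correctly specified fit have unit variance", {
  sp <- fitReadySpectrum(0.59, seed = 12, nPoints = 8192L)
  fit <- fitMap(sp, nPeaks = 2, degree = 0)
  n <- 2 * fit@nPoints
  chi2red <- (-2 * fit@logLik - n * log(2 * pi * fit@noiseSd^2)) / n
  expect_gt(chi2red, 0.8)
  expect_lt(chi2red, 1.2)
})

test_that("initialising at the truth converges immediately", {
  truth <- data.frame(position = c(-62.4, -61.6), fwhm = c(70, 90),
                      area = c(0.41, 0.59), phase = 0, label = c("U", "F"))
  sp <- freqDomainSpectrum(truth, noiseSd = 1e-8)
  init <- mkModel(truth)
  fit <- fitMap(sp, nPeaks = 2, degree = -1, init = init)
  expect_true(fit@converged)
  pk <- peakTable(fit)[order(peakTable(fit)$position), ]
  expect_equal(pk$area, c(0.41, 0.59), tolerance = 1e-6)
})

test_that("BIC model selection finds the true peak count, order-invariantly", {
  # one-peak truth
  sp1 <- fitReadySpectrum(0, seed = 2)
  cands <- expand.grid(nPeaks = 1:2, degree = 0, broad = FALSE)
  sel1 <- selectModel(sp1, cands)
  expect_identical(nrow(peakTable(sel1)), 1L)

  # two-peak truth at the experimental SNR
  sp2 <- fitReadySpectrum(0.59, seed = 2)
  sel2 <- selectModel(sp2, cands)
  expect_identical(nrow(peakTable(sel2)), 2L)

  # candidate order cannot matter
  sel2r <- selectModel(sp2, cands[rev(seq_len(nrow(cands))), ])
  expect_identical(peakTable(sel2r), peakTable(sel2))
  expect_error(selectModel(sp2, cands[0, ]), "non-empty")
})

test_that("BIC selection of the true model sharpens with record length", {
  hits <- vapply(c(1024L, 2048L, 4096L), function(np) {
    ok <- vapply(1:3, function(s) {
      sp <- fitReadySpectrum(0.59, seed = s, nPoints = np)
      nrow(peakTable(selectModel(sp, expand.grid(nPeaks = 1:2, degree = 0,
                                                 broad = FALSE)))) == 2L
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_equal(hits[3], 1)
  expect_true(all(diff(hits) >= 0))
})

test_that("populations come from state areas only, never broad or baseline", {
  pk <- data.frame(position = c(-62.4, -61.6), fwhm = c(70, 90),
                   area = c(41, 59), phase = 0, label = c("U", "F"))
  fit <- new("FitResult", model = mkModel(pk),
             posterior = matrix(numeric(0), 0, 8), chainId = integer(0),
             logLik = 0, bic = 0, rhat = numeric(0), noiseSd = 1,
             nPoints = 100L, converged = TRUE, flags = character(0))
  expect_equal(foldedFraction(populationsFromFit(fit)), 0.59)

  # equal areas give 0.5 regardless of a huge broad component
  pk$area <- c(5, 5)
  br <- data.frame(position = -62, fwhm = 1500, area = 1000, phase = 0,
                   label = "broad")
  fit@model <- mkModel(pk, broad = br)
  expect_equal(foldedFraction(populationsFromFit(fit)), 0.5)

  fit@model <- mkModel(pk[1, ])
  expect_error(populationsFromFit(fit), "population undefined")
})

test_that("fitting the transformed FID recovers the time-domain truth", {
  # time/frequency equivalence on noiseless records across phases; the
  # sampled FID differs from the continuous lineshape by the
  # discretisation of the decay (about dwell * R2, ~2% here), which
  # cancels in the population ratio
  for (ph in c(0, 0.4)) {
    tr <- groundTruthSpectrum(0.3, phase = ph)
    sp <- fourierTransform(simulateFid(tr), zeroFillFactor = 1L)
    sp@noiseSd <- 1e-6
    fit <- fitMap(sp, nPeaks = 2, degree = 0)
    pk <- peakTable(fit)[order(peakTable(fit)$position), ]
    expect_equal(pk$position, c(-62.4, -61.6), tolerance = 1e-4)
    expect_equal(pk$fwhm, c(70, 90), tolerance = 0.02)
    expect_equal(pk$area, c(0.7, 0.3), tolerance = 0.02)
    expect_equal(pk$phase, c(ph, ph), tolerance = 0.02)
    pf <- foldedFraction(populationsFromFit(fit))
    expect_equal(pf, 0.3, tolerance = 0.02)
  }
})

test_that("populations are invariant to a global phase rotation", {
  sp <- fitReadySpectrum(0.59, seed = 7)
  rot <- sp
  rot@values <- sp@values * exp(0.6i)
  p1 <- foldedFraction(populationsFromFit(fitMap(sp, 2, 0)))
  p2 <- foldedFraction(populationsFromFit(fitMap(rot, 2, 0)))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("posterior sampling is seeded, converged and calibrated", {
  truth <- data.frame(position = c(-62.4, -61.6), fwhm = c(70, 90),
                      area = c(0.41, 0.59), phase = 0, label = c("U", "F"))
  sp <- freqDomainSpectrum(truth, noiseSd = 2.1e-4, seed = 3,
                           nPoints = 1024L)
  fit <- fitMap(sp, nPeaks = 2, degree = 0)
  hm1 <- samplePosterior(sp, fit, nChains = 2, nWarmup = 150, nDraws = 150,
                         seed = 9)
  hm2 <- samplePosterior(sp, fit, nChains = 2, nWarmup = 150, nDraws = 150,
                         seed = 9)
  expect_identical(posteriorDraws(hm1), posteriorDraws(hm2))
  expect_true(all(hm1@rhat < 1.05))

  # every parameter's posterior mean lies within 3 posterior sd of truth
  # (peaks matched to the truth by position, since fit order follows the
  # peak picker)
  post <- posteriorDraws(hm1)[, 1:8]
  ord <- order(colMeans(post)[c("pos1", "pos2")])  # upfield (U) first
  cols <- as.vector(vapply(ord, function(k)
    paste0(c("pos", "fwhm", "area", "phase"), k), character(4)))
  truthNat <- c(-62.4, 70, 0.41, 0, -61.6, 90, 0.59, 0)
  z <- abs(colMeans(post)[cols] - truthNat) / apply(post[, cols], 2, sd)
  expect_true(all(z < 3))

  pop <- populationsFromFit(hm1)
  expect_gt(length(pop@draws), 0)
  expect_equal(pop@pF + pop@pU, 1, tolerance = 1e-12)
})
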