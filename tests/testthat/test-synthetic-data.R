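test_that("simulated FID honours the time-domain area convention", {
  tr <- groundTruthSpectrum(1, totalArea = 2.5,
                            positions = c(U = -62.4, F = -61.6))
  fid <- simulateFid(tr)
  # all area in F: |s(0)| equals the total area
  expect_equal(Mod(fid@points[1]), 2.5, tolerance = 1e-12)

  # two peaks, folded fraction recovered from spectral integrals within
  # grid/tail error (the Lorentzian wings of the two states overlap)
  tr2 <- groundTruthSpectrum(0.59)
  sp <- fourierTransform(simulateFid(tr2))
  mid <- -62.0
  hz <- sp@axis * sp@sfo
  re <- Re(sp@values)
  tz <- function(sel) -sum(diff(hz[sel]) * (head(re[sel], -1) +
                                              tail(re[sel], -1)) / 2)
  aU <- tz(sp@axis < mid)
  aF <- tz(sp@axis >= mid)
  expect_equal(aF / (aF + aU), 0.59, tolerance = 0.05)
  expect_equal(aF + aU, 1, tolerance = 0.01)
})

test_that("pure-noise FID has the requested noise level and is seeded", {
  acq <- acquisitionParams(nPoints = 8192L, dwell = 0.35 / 8192)
  tr <- groundTruthSpectrum(0.5, totalArea = 0, noiseSd = 0.37)
  fid <- simulateFid(tr, acq, seed = 21)
  expect_equal(sd(Re(fid@points)), 0.37, tolerance = 0.05)
  expect_equal(sd(Im(fid@points)), 0.37, tolerance = 0.05)
  # determinism: identical truth + seed is bit-identical
  expect_identical(fid@points, simulateFid(tr, acq, seed = 21)@points)
  expect_false(identical(fid@points, simulateFid(tr, acq, seed = 22)@points))
})

test_that("generated FID obeys Parseval's identity against its transform", {
  tr <- groundTruthSpectrum(0.4, noiseSd = 1e-3)
  fid <- simulateFid(tr, seed = 3)
  for (zf in c(1L, 2L)) {
    sp <- fourierTransform(fid, zeroFillFactor = zf)
    x <- fid@points
    x[1] <- x[1] / 2
    lhs <- sum(Mod(x)^2) * fid@dwell
    dnu <- abs(diff(sp@axis[1:2])) * sp@sfo
    # the area-preserving normalisation scales the spectrum by 2*dwell,
    # so the frequency-domain sum carries the constant 4
    rhs <- sum(Mod(sp@values)^2) * dnu / 4
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("CSP series follows fast-exchange population averaging", {
  expect_equal(simulateCspSeries(0, 8.50, 8.40)$delta_obs, 8.40)
  expect_equal(simulateCspSeries(1, 8.50, 8.40)$delta_obs, 8.50)
  expect_equal(simulateCspSeries(0.5, 8.50, 8.40)$delta_obs, 8.45)
  expect_error(simulateCspSeries(1.2, 8.5, 8.4), "\\[0, 1\\]")
  expect_error(simulateCspSeries(0.5, 8.4, 8.4), "differ")
  s1 <- simulateCspSeries(c(0.2, 0.8), 8.5, 8.4, noiseSd = 0.01, seed = 5)
  expect_identical(s1, simulateCspSeries(c(0.2, 0.8), 8.5, 8.4,
                                         noiseSd = 0.01, seed = 5))
})

test_that("intensity profiles are complementary logistics with shared noise", {
  # step limit: infinite steepness splits lengths across the onset
  st <- simulateIntensityProfile(onsetL = 34, steepness = Inf,
                                 lengths = c(31, 37))
  fRel <- st$F$volume / (st$F$n_scans * st$F$concentration * 100)
  expect_equal(sort(unique(fRel)), c(0, 1))

  # complementarity at zero noise
  sim <- simulateIntensityProfile(onsetL = 34,
                                  lengths = c(21, 31, 34, 37, 42, 67))
  relF <- sim$F$volume[match(sim$truth$linker_L, sim$F$linker_L)] /
    (256 * 100)
  relU <- sim$U$volume[match(sim$truth$linker_L, sim$U$linker_L)] /
    (256 * 100)
  expect_equal(relF + relU, rep(1, nrow(sim$truth)), tolerance = 1e-12)

  # concentration noise is shared between channels at each length
  simN <- simulateIntensityProfile(onsetL = 34, lengths = c(21, 34, 67),
                                   concNoiseFrac = 0.1, seed = 9)
  expect_equal(unique(simN$U$concentration), unique(simN$F$concentration))

  expect_error(simulateIntensityProfile(lengths = numeric()), "non-empty")
  expect_error(simulateIntensityProfile(lengths = c(31, 31)),
               "strictly increasing")
})

test_that("noiseless logistic profile inverts to the generating onset", {
  sim <- simulateIntensityProfile(onsetL = 34,
                                  lengths = c(21, 31, 34, 37, 42, 67))
  prof <- relativeProfile(sim$F, c(674, 695, 738, 743), referenceL = 67)
  expect_equal(foldingOnset(prof)$onset, 34, tolerance = 1e-3)
})

test_that("toy ensembles honour the mobility contract", {
  # zero mobility: every frame identical, downstream S2 exactly 1
  ens0 <- simulateEnsemble(ensembleSpec(nFrames = 6, ncLength = 8,
                                        mobility = rep(0, 8), seed = 2))
  expect_identical(ens0@coords[, , 1], ens0@coords[, , 6])
  expect_equal(orderParameters(ens0)$s2, rep(1, 8), tolerance = 1e-9)

  # single frame: contact frequencies can only be 0 or 100
  ens1 <- simulateEnsemble(ensembleSpec(nFrames = 1, ncLength = 8,
                                        mobility = rep(0.5, 8), seed = 2))
  cm <- contactFrequencies(ens1, cutoff = 6)
  expect_true(all(cm$frequency %in% c(0, 100)))

  # determinism
  spec <- ensembleSpec(nFrames = 4, ncLength = 6, seed = 11)
  expect_identical(simulateEnsemble(spec)@coords,
                   simulateEnsemble(spec)@coords)

  expect_error(ensembleSpec(nFrames = 0), ">= 1")
  expect_error(ensembleSpec(ncLength = 4, mobility = c(2, 0, 0, 0)),
               "\\[0, 1\\]")
})

test_that("generated artifacts round-trip through their readers", {
  tr <- groundTruthSpectrum(0.3, noiseSd = 0.01)
  fid <- simulateFid(tr, seed = 8, nScans = 128L)
  p <- withr::local_tempfile(fileext = ".csv")
  writeFid(fid, p)
  back <- readFid(p)
  expect_identical(back@points, fid@points)
  expect_identical(back@dwell, fid@dwell)
  expect_identical(back@nScans, fid@nScans)
  expect_identical(back@nucleus, fid@nucleus)

  sp <- withNoiseEstimate(fourierTransform(fid), list(c(-63.5, -60.5)))
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeSpectrum(sp, p2)
  back2 <- readSpectrum(p2)
  expect_identical(back2@values, sp@values)
  expect_identical(back2@axis, sp@axis)
  expect_identical(back2@noiseSd, sp@noiseSd)

  ens <- simulateEnsemble(ensembleSpec(nFrames = 3, ncLength = 5, seed = 6))
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePdb(ens, p3)
  back3 <- readEnsemblePdb(p3, roles = c(N = "NC", W = "rRNA:wall",
                                         P = "protein:uL23",
                                         Q = "protein:uL24"))
  expect_identical(back3@coords, ens@coords)
  expect_identical(back3@atoms$role, ens@atoms$role)
})
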