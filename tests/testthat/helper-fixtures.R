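# Shared fixtures and independent oracles for the test suite.

# Spectrum at the experimental regime: two peaks 0.8 ppm apart, target SNR
# on the dominant peak, unpadded transform, noise estimated from the
# baseline.
fitReadySpectrum <- function(pf, seed, snr = 20, nPoints = 4096L) {
  acq <- acquisitionParams(nPoints = nPoints, dwell = 0.35 / 4096)
  tr0 <- groundTruthSpectrum(pf)
  tr <- groundTruthSpectrum(pf, noiseSd = noiseForSnr(tr0, acq, snr = snr))
  sp <- fourierTransform(simulateFid(tr, acq, seed = seed),
                         zeroFillFactor = 1L)
  withNoiseEstimate(sp, list(c(-63.5, -60.5)))
}

# Frequency-domain synthetic: data generated from the fitted model family
# itself (round-trip identity conditions, no sampling discretisation).
freqDomainSpectrum <- function(peaks, noiseSd = 1e-8, seed = 1,
                               nPoints = 4096L, baseline = complex(0)) {
  acq <- acquisitionParams(nPoints = nPoints, dwell = 0.35 / 4096)
  sw <- 1 / acq@dwell
  hz <- seq(sw / 2, -sw / 2 + sw / nPoints, length.out = nPoints)
  ax <- acq@carrier + hz / acq@sfo
  m <- new("LineshapeModel", peaks = peaks, broad = NULL,
           baseline = baseline)
  vals <- modelSpectrum(m, ax, acq@sfo)
  set.seed(seed)
  vals <- vals + complex(real = rnorm(nPoints, sd = noiseSd),
                         imaginary = rnorm(nPoints, sd = noiseSd))
  new("Spectrum1D", values = vals, axis = ax, sfo = acq@sfo,
      noiseSd = noiseSd)
}

# Trapezoidal integral of the real channel over Hz.
trapzReHz <- function(spec, ppmRange = range(spec@axis)) {
  sel <- spec@axis >= min(ppmRange) & spec@axis <= max(ppmRange)
  hz <- spec@axis[sel] * spec@sfo
  y <- Re(spec@values[sel])
  abs(sum(diff(hz) * (head(y, -1) + tail(y, -1)) / 2))
}

# O(n^2) all-pairs contact oracle, independent of the cell-list kernel.
bruteForceContacts <- function(ens, cutoff) {
  at <- atomTable(ens)
  heavy <- toupper(at$element) != "H"
  comps <- setdiff(unique(at$role), "NC")
  resnos <- sort(unique(at$resno[at$role == "NC" & heavy]))
  out <- expand.grid(nc_residue = resnos, component = comps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$frequency <- 0
  for (f in seq_len(nFrames(ens))) {
    xyz <- frameCoords(ens, f)
    for (i in seq_len(nrow(out))) {
      nc <- which(at$role == "NC" & at$resno == out$nc_residue[i] & heavy)
      pt <- which(at$role == out$component[i] & heavy)
      hit <- FALSE
      for (a in nc) {
        d2 <- (xyz[pt, 1] - xyz[a, 1])^2 + (xyz[pt, 2] - xyz[a, 2])^2 +
          (xyz[pt, 3] - xyz[a, 3])^2
        if (any(d2 < cutoff^2)) { hit <- TRUE; break }
      }
      if (hit) out$frequency[i] <- out$frequency[i] + 100 / nFrames(ens)
    }
  }
  out
}

# Hand-rolled ordinary least squares (closed form), oracle for
# energyCorrelation.
handOls <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  ss <- sum((y - a - b * x)^2)
  list(slope = b, intercept = a,
       r2 = 1 - ss / sum((y - mean(y))^2))
}

# Build a minimal ensemble by hand: one NC residue whose C->O unit vector
# is given per frame, plus a single far-away wall atom.
handEnsemble <- function(unitVectors) {
  nf <- nrow(unitVectors)
  atoms <- data.frame(eleno = 1:4, name = c("CA", "C", "O", "ZZ"),
                      resno = c(1L, 1L, 1L, 99L),
                      resname = c("GLY", "GLY", "GLY", "WAL"),
                      chain = c("N", "N", "N", "W"),
                      element = c("C", "C", "O", "C"),
                      role = c("NC", "NC", "NC", "rRNA:wall"),
                      stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(4, 3, nf))
  for (f in seq_len(nf)) {
    u <- unitVectors[f, ] / sqrt(sum(unitVectors[f, ]^2))
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- c(0.5, 0, 0)
    coords[3, , f] <- c(0.5, 0, 0) + 1.23 * u
    coords[4, , f] <- c(50, 50, 50)
  }
  new("StructureEnsemble", atoms = atoms, coords = coords)
}

# Populations printed for the uL23/uL24 variants at L = 31 and 34 (1% cap
# where no folded state was detected), used by the worked examples.
printedPopulations <- function() {
  list(
    L31 = c(WT = 0.08, `23dL` = 0.11, `24dL` = 0.16, `23dL24dL` = 0.42,
            `23pL` = 0.34, `24pL` = 0.01, `23pL24pL` = 0.01),
    L31bounded = c("24pL", "23pL24pL"),
    L34 = c(WT = 0.59, `23dL` = 0.67, `24dL` = 0.64, `23dL24dL` = 0.72,
            `23pL` = 0.66, `24pL` = 0.47, `23pL24pL` = 0.47))
}
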