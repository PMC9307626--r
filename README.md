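# rncfold

Quantitative analysis of co-translational protein folding on
ribosome–nascent chain complexes (RNCs), for structural biologists and NMR
spectroscopists who measure how the geometry of the ribosomal exit tunnel
modulates nascent-chain folding.

When a protein domain such as an immunoglobulin-like filamin domain is
arrested on the ribosome with a defined linker length *L* between its
C-terminus and the peptidyl transferase centre, 1D ¹⁹F NMR resolves its
folded (F) and unfolded (U) states as two resonances in slow exchange
(k_ex ≪ |δ_U − δ_F|). Peak integrals then report the state populations
directly, and the folding free energy follows from

    ΔG_F-U = −RT · ln(P_F / P_U),      ΔΔG_F-U = ΔG_mutant − ΔG_WT

`rncfold` implements the full analysis chain around this relation:

- **Lineshape deconvolution** (`fitMap`, `selectModel`, `samplePosterior`,
  `populationsFromFit`): joint fitting of the real and imaginary spectral
  channels to a mixture of complex Lorentzians
  `2 a e^{iφ} / (π w + i 2π(ν − ν₀))` (area *a*, FWHM *w* Hz) plus an
  optional broad background component and a complex polynomial baseline;
  model complexity chosen by BIC (`k·log n − 2·log L̂`); uncertainties by
  an in-package Hamiltonian Monte Carlo sampler with split-R̂ diagnostics.
  The broad component and baseline never enter population sums.
- **Thermodynamics** (`deltaGFolding`, `ddgFolding`, `propagateError`,
  `detectionBound`, `lengthAttenuation`): free energies with delta-method
  or Monte Carlo error propagation, 1%-cap detection-limit bounds for
  spectra with no visible folded state, and the mean percentage
  attenuation of ΔΔG between linker lengths.
- **Binding analysis** (`cspPopulation`, `ddgBinding`,
  `energyCorrelation`): fast-exchange chemical-shift perturbations
  converted to bound/unbound populations, binding free-energy changes
  (weaker binding ⇒ positive ΔΔG), and the folding–binding OLS
  correlation.
- **Intensity profiles** (`relativeProfile`, `foldingOnset`,
  `movingAverage`, `fFL`): per-residue cross-peak volumes normalised by
  scan count and nascent-chain concentration into relative U/F intensity
  profiles, threshold-crossing folding onsets with bound reporting, and
  arrest-peptide force-assay fractions FL/(FL+A).
- **Ensemble statistics** (`tunnelVolume`, `volumeDifference`,
  `contactFrequencies`, `orderParameters`): sphere-seeded grid volumes of
  the exit tunnel (20 Å seed spheres, 2.0 Å grid, 1.09 Å exclusion
  cutoff plus Bondi vdW radii), nascent-chain–ribosome heavy-atom contact
  frequencies (% of frames), and S² order parameters of backbone
  carbonyls from multi-model PDB ensembles.
- **Synthetic data** (`simulateFid`, `simulateCspSeries`,
  `simulateIntensityProfile`, `simulateEnsemble`): generators for every
  input with known ground truth, so each stage is testable by parameter
  recovery.

## Worked example

Simulate a ¹⁹F RNC spectrum at the experimental regime (two peaks 0.8 ppm
apart on a 470.4 MHz axis, SNR ≈ 20, true folded fraction 0.59), recover
the populations, and convert to a folding free energy:

```r
library(rncfold)

truth <- groundTruthSpectrum(foldedFraction = 0.59)
truth <- groundTruthSpectrum(0.59, noiseSd = noiseForSnr(truth, snr = 20))
fid   <- simulateFid(truth, seed = 7)
fid
#> Fid: 4096 complex points, dwell 8.54e-05 s (aq 0.35 s), 19F at 470.4 MHz, 1 scan(s)

spec <- fourierTransform(fid, zeroFillFactor = 1)
spec <- withNoiseEstimate(spec, exclusionWindows = list(c(-63.5, -60.5)))
fit  <- selectModel(spec)                       # BIC over candidate models
fit  <- samplePosterior(spec, fit, nChains = 4, nWarmup = 500,
                        nDraws = 500, seed = 7) # HMC uncertainties
pop  <- populationsFromFit(fit)
pop
#> StatePopulations: pF = 0.5946 +/- 0.0048, pU 0.4054 (source: posterior)

deltaGFolding(pop, variant = "WT", linkerL = 34)
#>   variant linker_L        dg       sd bounded direction temperature
#> 1      WT       34 -0.226902 0.011771   FALSE        ==      298.15

frequencySeparation(0.8, sfo1H = 500.13, nucleus = "19F")
#> [1] 376.3778
```

The recovered population (0.595 ± 0.005) agrees with the generating truth
within its posterior uncertainty; the free energy is in kcal/mol at
298.15 K, and the 376 s⁻¹ separation is what makes the two-state slow-
exchange integration valid. `runPipeline()` wires the same stages (plus
the profile and ensemble analyses) into a single seeded, manifest-writing
run from a YAML/JSON configuration.

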