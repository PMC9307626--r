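---
title: "Quantifying co-translational folding: models, priors and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-translational folding: models, priors and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rncfold)
```

# The measurement and its model

A ribosome–nascent chain complex (RNC) carries a folding-competent domain
tethered to the peptidyl transferase centre by a linker of *L* residues.
With a trifluoromethyl label in the domain, 1D ¹⁹F NMR shows one resonance
for the unfolded (U) and one for the folded (F) state, separated here by
0.8 ppm. On a 470.4 MHz ¹⁹F axis that separation is

```{r}
frequencySeparation(0.8, sfo1H = 500.13, nucleus = "19F")
```

about 376 s⁻¹, far above the interconversion rate — the states are in slow
exchange, so each resonance integrates to its population. The two-state
thermodynamics is then

$$\Delta G_{F\text{-}U} = -RT\,\ln\frac{P_F}{P_U},$$

evaluated at 298.15 K (the ¹⁹F acquisition temperature; ¹⁵N-derived
quantities can override the temperature through `thermoConfig()`). Every
energy output records its temperature, and functions refuse to combine
energies computed at different temperatures.

## The lineshape model

An exponentially decaying resonance with time-domain amplitude (area) $a$,
frequency $\nu_0$, phase $\phi$ and decay rate $R_2 = \pi w$ ($w$ = FWHM in
Hz) has the one-sided Fourier transform

$$P(\nu) = \frac{2\,a\,e^{i\phi}}{\pi w + i\,2\pi(\nu - \nu_0)},$$

normalised so that the integral of the absorptive (real, $\phi = 0$)
component over frequency equals $a$, the FWHM is $w$, and the peak height
is $2a/(\pi w)$. A spectrum model (`modelSpectrum`) is a sum of such peaks
— the U and F state peaks, optionally a broad background component with
FWHM constrained to at least 500 Hz that absorbs signal from exchange-
broadened intermediate states — plus a complex polynomial baseline of
degree at most 3 evaluated on the axis rescaled to $[-1, 1]$. The broad
component and the baseline are bookkeeping, never biology: they are
excluded from all population sums.

Fitting happens in the frequency domain, jointly on the real and imaginary
channels. For this model class with stationary Gaussian noise the
frequency-domain joint fit is likelihood-equivalent to fitting the two FID
components directly (the discrete Fourier transform is an orthogonal
change of basis up to a known constant), and it makes the polynomial
baseline interpretable as a spectral artefact model.

Two numerical facts shape the defaults:

- **Zero-filling correlates noise.** Interpolated points added by
  zero-filling carry no new information; treating them as independent
  observations understates every posterior width by about $\sqrt{2}$ at a
  zero-fill factor of 2. Quantitative fits therefore run on the unpadded
  transform (`zeroFillFactor = 1`); zero-filling is cosmetic.
- **Sampling discretisation.** The DFT of a dwell-sampled decaying
  exponential differs from the continuous Lorentzian by $O(R_2\,\Delta t)$
  — here 1–2% on individual widths and areas. The bias largely cancels in
  the population ratio $P_F = a_F/(a_F + a_U)$, which is the quantity of
  record; recovered populations are unbiased to well below their
  uncertainties at the working SNR. No apodization is applied before
  fitting, because windowing biases exactly those areas.

## Point estimation and model choice

`fitMap` runs Levenberg–Marquardt least squares on the concatenated
(real, imaginary) residual, weighted by the spectral noise sd, with an
analytic Jacobian computed in compiled code. The noise sd is estimated
once, as $1.4826 \times \mathrm{MAD}$ of baseline points
(`estimateNoise`), and held fixed. Initial values come from an iterative
peak picker; because a weak state peak (the folded state near its
detection limit has peak SNR ≈ 1.4 when the dominant peak is at SNR 20)
can trap the optimiser on a noise feature, the fit re-seeds the
smallest-area peak at the largest residual and keeps the refit only when
the deviance improves. Fitted areas are normalised to be non-negative by
folding signs into the phase, and phases are wrapped into $(-\pi, \pi]$.

Model complexity — number of state peaks, baseline degree, presence of the
broad component — is chosen by the Bayesian information criterion,
$\mathrm{BIC} = k \ln n - 2 \ln \hat L$ with $n = 2\times$ the number of
spectral points. Ties break toward fewer parameters, and candidates are
ordered internally so the selection cannot depend on the order of the
candidate list. U/F labels are assigned by proximity to configurable
reference shifts (defaults 0.8 ppm apart); if both references point at
the same peak, the downfield peak is taken as F.

## Posterior sampling

`samplePosterior` implements Hamiltonian Monte Carlo with leapfrog
integration. Priors: peak positions uniform over the spectral window;
FWHM log-uniform on [1, 2000] Hz (broad component: [500, 20000] Hz); areas
half-normal scaled to the total spectral integral; phases uniform
(exploiting the $2\pi$ periodicity of the likelihood); baseline
coefficients normal with sd $10\times$ the noise sd. Positions and
linewidths are mapped to unconstrained coordinates by logistic
transforms, areas by logs, with the Jacobians included in the target
density.

The step size adapts by dual averaging during warmup toward an 0.8
acceptance rate, with the leapfrog step count randomised in [8, 20]. The
mass matrix is dense: the Gauss–Newton Hessian of the negative log
posterior at the MAP (built from the same analytic Jacobian as the
optimiser), pushed to the unconstrained coordinates. This matters — the
posterior mixes scales spanning four orders of magnitude (ppm positions
known to $10^{-4}$ next to diffuse baseline coefficients) with strong
area–baseline correlations, and a diagonal mass leaves such a target
effectively frozen. With the Hessian mass all split-R̂ values sit at
1.00; any value above 1.01 flags the result, and more than 5% divergent
trajectories (Hamiltonian error > 100) raises an error rather than
returning a silently unreliable posterior.

$P_F$ is evaluated per posterior draw; its posterior mean and sd are the
reported population and uncertainty. Posterior widths are calibrated:
across repeated synthetic spectra the posterior sd of $P_F$ matches the
frequentist scatter of the point estimates, and central 95% intervals
cover the truth in the test suite's 50-replicate coverage check.

## Detection limits and error propagation

When no folded-state peak is visible, `detectionBound` converts the
spectral noise into the largest population that could have escaped
detection: a peak of height $k\sigma$ (default $k = 3$) with the U-state
linewidth has area $k\sigma\pi w_U/2$, and the bound is that area over
the total, capped at 1%. Such populations are marked `bounded`; the
derived free energies carry a "≥" direction, propagate through
differences as inequalities, and can never slip silently into means or
regressions — `lengthAttenuation` includes them only under its documented
default flag, and `energyCorrelation` drops them with a message or
refuses them outright.

`propagateError` offers the delta method,
$\mathrm{sd}(\Delta G) = RT\,\mathrm{sd}(P_F)/(P_F(1-P_F))$, and Monte
Carlo propagation through a truncated normal. Exact large-sample
computation shows the two agree within 10% for population sds up to 0.05
across $P_F \in [0.2, 0.8]$, and up to sd 0.1 at mid populations where
the logit's curvature vanishes; outside that region the delta method
genuinely underestimates (the tests verify the disagreement exceeds 10%
at $P_F = 0.2$, sd 0.1) because the log-odds transform is convex and
heavy-tailed there. The Monte Carlo mode is the honest choice near the
edges.

## Binding analysis

For the C-terminal segment of the unfolded chain exchanging rapidly
between ribosome-bound and unbound states, the observed shift is the
population-weighted average of the two reference shifts, so
$p_b = (\delta_{obs} - \delta_{ub})/(\delta_b - \delta_{ub})$
(`cspPopulation`). The fully-bound reference shift must be supplied by
the user; no default is invented. Binding free energies use the same
two-state formula, with the sign convention that weaker binding on a
variant ribosome gives a positive $\Delta\Delta G_{binding}$ — fixed this
way so that loop-truncation variants, which release the nascent chain,
come out positive. `energyCorrelation` reports the OLS $R^2$ and slope of
binding against folding changes.

## Intensity profiles and folding onset

`relativeProfile` normalises per-residue cross-peak volumes by scan count
and relative nascent-chain concentration, averages over marker residues
(defaults: V682/A683/A694 for the ¹⁵N unfolded channel, I674/I695/I738/
I743 for the ¹³C folded channel), and references the fully unfolded
(U channel, shortest linker) or fully folded (F channel, longest linker)
record, so the reference point is 1 by construction. Volume and
concentration uncertainties combine in quadrature as relative errors.

The folding onset is defined as the smallest linker length at which
linear interpolation between adjacent measured points crosses 0.5 — a
deliberate, machine-checkable construction, since onsets are usually
reported qualitatively ("< 30", "~35"). When the profile never brackets
the threshold the estimator returns an explicit bound (`"<Lmin"` or
`">Lmax"`) instead of an extrapolated number. The four-point moving
average (`movingAverage`) is a display aid and never feeds the onset
estimator. `fFL` computes arrest-peptide force-assay fractions
FL/(FL + A) with replicate means and sds.

## Ensemble statistics

`tunnelVolume` follows the sphere-seeded grid protocol: 20 Å inclusion
spheres at nascent-chain Cα positions, a cubic grid of 2.0 Å pitch over
their bounding box, and deletion of grid points within (vdW radius +
1.09 Å) of any structure atom. The exclusion semantics are a documented
choice: the cutoff is interpreted as padding on Bondi vdW radii — the
usual intent of grid-exclusion pocket-volume tools — with a
`mode = "center"` switch for plain centre-distance exclusion to preserve
comparability with either convention.
Unknown elements fall back to 1.7 Å with a warning; hydrogens are
ignored by default. The unoccluded single-sphere volume reproduces
$\tfrac{4}{3}\pi r^3$ within 1.2% at the default spacing and converges
under grid refinement. `volumeDifference` evaluates both structures on
the identical seed-anchored grid, so differences isolate the structural
change; the grid is axis-aligned, hence exactly invariant under
translations and invariant under rotations only up to grid error.

`contactFrequencies` reports, per nascent-chain residue and ribosomal
component, the percentage of frames with any heavy-atom pair within
4.5 Å — the common heavy-atom contact convention, configurable since no
single cutoff is canonical. The implementation uses a
cell-list spatial partition in compiled code and is tested to agree
exactly with a brute-force all-pairs oracle.

`orderParameters` computes, per residue, the generalised order parameter
of the backbone carbonyl C→O unit vector $u$ from its second moments over
frames:

$$S^2 = \tfrac{3}{2}\left(\langle x^2\rangle^2 + \langle y^2\rangle^2 +
\langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
2\langle yz\rangle^2\right) - \tfrac{1}{2}.$$

$S^2 = 1$ for a rigid vector, $0.25$ for two orthogonal orientations with
equal weight, and $\to 0$ in the isotropic limit. Averages run over the
full ensemble with no internal-motion windowing; the laboratory frame is
fixed because the ribosome is frozen across frames, so no alignment is
performed.

# The synthetic-data generator

The generator exists so that every stage is testable by parameter
recovery; its defaults are the study conditions, chosen once:

- **Spectra**: two peaks 0.8 ppm apart at U = −62.4 / F = −61.6 ppm on a
  470.4 MHz ¹⁹F axis (0.9407 × 500.13 MHz), linewidths 70 (U) and 90 (F)
  Hz within the experimental 60–150 Hz range, 4096 complex points over a
  350 ms acquisition, i.i.d. circular complex Gaussian noise. The
  spectral SNR is not reported for the original data; the default of 20
  on the dominant peak (`noiseForSnr`) is chosen for test stability and
  is stated as such, not as fidelity.
- **CSP series**: population-weighted shifts with Gaussian noise.
- **Intensity profiles**: a logistic folded fraction in *L* with
  configurable midpoint and steepness, the unfolded channel its
  complement, and multiplicative concentration noise drawn once per
  length and applied identically to both channels — emulating shared
  western-blot concentration errors.
- **Ensembles**: a self-avoiding jointed chain (CA/C/O pseudo-atoms,
  3.8 Å steps) threaded through a rigid pseudo-atom cylinder (radius
  13 Å) with two small protruding "loop" clusters, written/read as
  multi-model PDB. Per-residue `mobility` ∈ [0, 1] interpolates between
  identical frames (mobility 0) and isotropic carbonyl orientations with
  positional jitter (mobility 1). Coordinates are rounded to 0.001 Å so
  the PDB round trip is lossless. The wall makes no attempt to mimic
  rRNA geometry — only the statistics operators are under test.

What passing tests on these synthetics do **not** show: recovery under
non-Lorentzian lineshapes (chemical-exchange broadening, field
inhomogeneity), baseline distortions beyond degree-3 polynomials,
correlated spectral noise, real tunnel electrostatics, or the
conformational statistics of real nascent chains. The printed
tunnel-volume increases for the engineered-loop ribosomes depend on
homology-modelled loop structures that are not deposited, so they are
exercised qualitatively (loop deletion opens volume, double deletion
more) rather than reproduced numerically.

# Degenerate inputs and tie-breaks

State peaks closer than $10^{-3}$ ppm are flagged as a collision rather
than silently merged. A fit that exhausts its restarts returns with
`converged = FALSE` and its best residual instead of erroring. Population
conversion refuses fits without exactly one U and one F peak and directs
the caller to the detection-bound path. $P_F \in \{0, 1\}$ raises an
infinite-energy error rather than returning ±Inf. The onset estimator
handles rising and falling profiles symmetrically, so complementary U/F
channels give the same crossing. Zero spectral noise in the detection
bound returns the cap with a warning.

# Problem sizes in the shipped checks

The test suite and acceptance script size their simulations for a
single-CPU run: full-resolution spectra (4096 points) with 4×1000+1000
HMC for the headline population recoveries, 1024-point spectra with
2×200+200 HMC for the 50-replicate coverage check, ensembles of tens of
frames (thousands only for isotropic-limit checks), and 1–2 Å grids over
single-seed spheres. These sizes are the package's choices for routine
verification; all of them scale up by argument.
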