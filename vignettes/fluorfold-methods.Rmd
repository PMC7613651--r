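---
title: "Quantifying co-translational folding from 1D 19F NMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-translational folding from 1D 19F NMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorfold)
```

## The problem

A protein domain folding on the ribosome populates several conformational
states at once: an unfolded chain (U), partially folded intermediates bound to
the ribosome surface (I1, I2), and the native fold (N). With a single
trifluoromethyl reporter on the nascent chain, each state contributes one
19F resonance, so a one-dimensional spectrum is a mixture of up to four
Lorentzian lines differing enormously in width — ~20–40 Hz for the mobile
unfolded chain, several hundred Hz for ribosome-associated intermediates.
Because chemical exchange between the states is slow (of order 1 s⁻¹ or
less, versus shift differences of hundreds of Hz), the lines superpose
independently and peak integrals are directly proportional to state
concentrations. Everything quantitative in this package follows from that:
populations from integrals, free energies from population ratios, exchange
rates from saturation transfer, and sample integrity from translational
diffusion.

## Signal model and processing

The time-domain signal is
$$s(t) = \sum_k A_k\, e^{i\phi_k} \exp\!\big(i 2\pi \nu_k t - \pi \Gamma_k t\big) + \varepsilon(t),$$
with amplitude $A_k$ proportional to population, offset frequency $\nu_k$
set by the chemical shift and carrier, and $\Gamma_k$ the full width at half
maximum in Hz. Synthetic data are generated with zero phase and i.i.d.
complex Gaussian receiver noise (`synth_fid()`), the standard white-noise
model, which makes the frequency-domain noise level analytically known
($\sigma_f = \sigma_t \sqrt{N} / \mathrm{sw}$) and testable.

Processing mirrors conventional practice: exponential apodization
(`apodize()`, default 10 Hz, adding exactly that amount to every line width),
zero-filling and Fourier transform with first-point scaling so that peak
integrals are preserved (`to_spectrum()`), optional polynomial baseline
correction against the broad fluoropolymer background of the probe
(`baseline_correct()`, order-3 polynomial on signal-masked points; a
rolling-minimum envelope is available as an alternative), and a robust
MAD-based noise estimate from a signal-free region (`estimate_noise()`).
Defaults that the underlying experiment does not pin down — zero-fill factor
2, zero-order phase only, the 20 ppm window centred at −62 ppm, the
470.4 MHz 19F frequency implied by a 500 MHz (1H) magnet — are declared
choices, not inferences.

One processing subtlety matters for inference. Apodization and zero-filling
correlate the spectral noise over a few points. For *display* that is
harmless; for *quantification* the package fits either the raw-spectrum
(`lb_hz = 0`, `zero_fill = 1`) frequency domain, where white time-domain
noise stays white, or the time domain directly. The residual bootstrap is
then correctly calibrated; on apodized spectra it resamples residuals in
moving blocks sized from the residual autocorrelation to compensate.

## Deconvolution and model choice

`fit_lorentzians()` solves the 3n-parameter nonlinear least-squares problem
(centre, width, area per component) by Levenberg–Marquardt with an analytic
Jacobian, areas constrained non-negative and widths to [5, 1000] Hz so that
no component degenerates into a baseline. Initialisation is greedy and
stagewise: fit k components, place component k+1 at the maximum of the
smoothed residual, refit. This finds broad shoulders that naive peak picking
misses; `pick_initial_peaks()` (smoothed local maxima, padding by splitting
the widest guess) remains available for resolved spectra.

`fit_time_domain()` fits the same model to the complex FID by variable
projection: the complex amplitudes enter linearly and are solved exactly at
every step, leaving a 2n-dimensional search over frequencies and widths with
a Kaufman-approximation Jacobian. On noiseless data the two domains agree to
1e-6 in every parameter, which the test suite asserts.

The number of states is chosen in the time domain by the Bayesian
information criterion over n = 1…n_max models (`select_n_states()`), with
4n + 1 parameters per model under a Gaussian likelihood on stacked
real/imaginary residuals. BIC is used as a concrete, deterministic,
asymptotically consistent stand-in for a full Bayesian evidence calculation;
it is cheap and reproducible, and its calibration is checked empirically:
at a signal-to-noise ratio of 20 it selects n = 4 for the four-state
scenario in well over 90% of realisations.

Two fitting modes serve different questions:

* **Free fit** (`fit_lorentzians()` + `assign_states()`): no assumptions on
  which states exist. Labels follow the narrow/broad × shift-proximity rule
  (narrow near −61.8 ppm → U, narrow near −62.6 → N, broad → I1/I2 by the
  nearer reference), with a configurable 100 Hz width threshold — the
  broadness of intermediates is stated only qualitatively by the experiment,
  so the threshold is a declared default.
* **Templated fit** (`fit_states()`): one component per expected state with
  per-state parameter boxes — narrow components within ±0.06 ppm of the U/N
  references and widths below the threshold, intermediates within ±0.15 ppm
  of their references with widths in (100, 600] Hz. This encodes the prior
  that intermediates resonate *near* U and N respectively (that is what
  their shifts mean structurally) and removes the label-swapping degeneracy
  of the free fit. It is the mode used for population quantification across
  a construct series; states that are genuinely absent converge to near-zero
  area and are reported as below the detection limit rather than biasing the
  landscape. Width caps beyond 600 Hz were found to let an intermediate
  component absorb baseline, hence the tighter default.

## Uncertainties

`bootstrap_fit()` implements bootstrapping of residuals: resample the fit
residuals with replacement, add them to the fitted curve, refit from the
original solution, repeat B times. Refitting from the original solution
deliberately measures parameter uncertainty rather than basin-hopping
variability. Blocks rather than single points are resampled when the
residuals are autocorrelated (see above). Population standard deviations and
percentile intervals come from the replicate fractions; free-energy errors
are propagated by taking the bootstrap standard deviation of the log-ratio
itself, which preserves the negative correlation between compositional
fractions (a delta-method quadrature sum is the fallback when no samples are
available). Calibration is property-tested: nominal 68% intervals cover the
generator truth in 58–78% of synthetic replicates.

## Populations, detection limits and free energies

Fractions are integrals over the total integral (`populations_from_fit()`).
An expected state whose fitted fraction falls below the detection limit is
censored: the limit is the fractional area of the smallest peak of typical
width (default 100 Hz) whose height reaches 3 spectral noise standard
deviations, capped at 5% — the practical detection level of this kind of
measurement. Censoring converts into one-sided free-energy bounds:
$$\Delta G_{X-U} = -RT \ln(p_X / p_U),$$
with the censored population replaced by the limit, giving a lower bound
when X is unseen and an upper bound when U is unseen
(`delta_g()`, R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, T = 298 K, so RT =
0.5922 kcal/mol). `ddg()` differences two constructs with quadrature errors
and bound-direction bookkeeping; `build_landscape()` assembles the
ΔG-versus-linker-length table; `relative_to()` re-references to any state
available as a point estimate.

## Exchange kinetics

`exchange_model()` builds an N-site kinetic model with detailed balance
enforced to 1e-9; the default topology is a star through the unfolded state
(U↔I1, U↔I2, U↔N), since slow-exchange data of this kind cannot identify
the full pairwise rate matrix; a full generator can be supplied instead.
The pair convention is $k_{ex} = k_{fwd} + k_{bwd}$, split by equilibrium
populations.

`bm_matrix()`/`bm_propagate()` assemble and exponentiate the Bloch–McConnell
evolution over stacked (Mx, My, Mz) per site under continuous-wave
irradiation (no pulse shaping — the experiments use a weak constant B1).
`bm_cest()` normalizes saturated Mz against a far off-resonance reference.
Propagation accuracy is tested against adaptive ODE integration to 1e-8.

`fit_cest()` recovers the exchange rate by least squares with populations
and shifts fixed from the line-shape stage. When the profile shows no
significant cross-site dip, `kex_upper_bound()` instead reports the largest
rate whose predicted dip — *in excess of the zero-exchange prediction*, so
direct saturation spillover between nearby resonances does not masquerade as
transfer — stays within z = 2 noise standard deviations, found by bisection
on the forward model. τ_ex is reported as 1/k_ex throughout.

`r1rho_rate()` exposes both the two-site on-resonance closed form
$$R_{1\rho} = \bar R_2 + \frac{p_a p_b\, \Delta\omega^2\, k_{ex}}{k_{ex}^2 + \Delta\omega^2 + \omega_1^2}$$
(population-averaged $\bar R_2$) and a numeric rate for any N: the
amplitude-weighted decay rate of the non-oscillatory eigenmodes of the
observed site's spin-locked magnetization — the quantity a mono-exponential
fit of the decay actually measures, which matters when exchange mixes modes
of similar decay rate. The closed form carries no longitudinal-relaxation
term, so the numeric cross-validation uses R1 = 0, site-equal R2 models;
agreement is within 2% across random slow-exchange models.
`fit_r1rho()` fits the measured mono-exponential decays.

## Diffusion integrity check

`st_attenuation()` is the Stejskal–Tanner law
$\exp(-D \gamma^2 g^2 \delta^2 (\Delta - \delta/3))$ with the 19F
gyromagnetic ratio; trapezoidal gradient pulses are treated as
rectangular-equivalent (ramp times are not specified by the experiment and
the correction is a few percent, absorbed by the classification margins).
`fit_D()` inverts log-attenuation versus g² by least squares;
`classify_attachment()` compares D against defaults of 2.5×10⁻¹¹ m²/s
(slowest credible free domain is far above a ~2.3 MDa ribosomal particle by
Stokes–Einstein scaling) and 7×10⁻¹¹ m²/s, reporting attached / mixed /
released with a closed lower interval. With the standard two-gradient scheme
(0.027 and 0.513 T/m, Δ = 100 ms, δ = 4 ms) and 5% intensity noise, a
single two-point inversion carries ~20% statistical error; recovery within
10% refers to the mean over replicate measurements, which is how the check
is used in practice (interleaved throughout acquisition).

## The synthetic generator as study design

`length_scenario()` emulates the co-translational folding transition:
logistic U decay (midpoint 37 residues), logistic N rise (midpoint 46),
Gaussian intermediate bumps peaking at 31–34 (I1) and near 47 (I2) residues,
all gated to zero below 29 residues (complete emergence of the domain from
the exit tunnel) and floored at 2% before renormalisation so that short
linkers are exactly pure-U. These curve shapes are a design choice — the
experiments report trends, not a law. Default line widths are 25/180/220/45
Hz for U/I1/I2/N; the true intermediate widths are not published, so these
are free parameters of the generator, not measured values. The default
noise level used in the property tests corresponds to a spectral
signal-to-noise ratio of 20 on the tallest (unfolded) peak, typical of a
summed RNC dataset.

What passing tests on this generator do show: the estimator chain is
unbiased and correctly calibrated when its model class matches the data, at
realistic widths, separations and noise. What they cannot show: robustness
to phase errors, lineshape non-ideality (field inhomogeneity, probe
background only partially removed), intensity drift from sample degradation,
or exchange broadening — real-data effects outside the generator's model.
The sample-integrity operations (diffusion classification, total-integral
proportionality) are the package's guardrails for the first of these.

## Problem sizes and numerical choices

The property tests run at the full acquisition geometry (350 ms, 20 ppm at
470.4 MHz ⇒ 3293 complex points): 100 seeds for noisy recovery and model
selection, 200 outer replicates × B = 200 for bootstrap calibration, 100
random models for the propagator and R1ρ checks, 50 seeds × 10 linker
lengths × B = 100 for landscape recovery; unit tests use a reduced geometry
(10 ppm, 0.15 s) chosen so the whole suite stays fast without changing any
conclusion. Optimiser tolerances are 1e-12 on the cost with 500 (frequency)
/ 200 (time) iteration caps; an optimiser that stops on the iteration cap
with a plateaued cost (relative decrease < 1e-8 over the last 5 iterations,
as happens in the flat valleys of zero-area template components) is treated
as converged. Ties in state assignment break toward the nearer reference
shift. Degenerate inputs — flat spectra, all-censored populations, inverted
thresholds, non-decaying series — are rejected with informative errors
rather than silently fitted.

## Known limitations

* Lorentzian lines only; no Voigt/Gaussian shapes and no exchange-coupled
  line-shape fitting (justified by the slow-exchange regime, and verified
  within it by the R1ρ and CEST operations).
* BIC approximates the cited Bayesian evidence computation; component counts
  at very low signal-to-noise are conservative (underfitting merges a weak
  broad state into its neighbour — visible at folding-onset lengths, and the
  reason the templated fit exists for landscape work).
* Bounds use simple censoring at the detection limit, not a Bayesian
  censoring model.
* Each spectrum is fitted independently; no global shift/width sharing
  across constructs.
* The nmrPipe binary format is not read or written; interchange is through
  plain-text tables with JSON sidecars.
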