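# fluorfold

Quantitative analysis of one-dimensional ¹⁹F NMR data from ribosome–nascent
chain complexes (RNCs): detecting the folding states a nascent protein domain
populates during biosynthesis and measuring their thermodynamics and kinetics.

## The scientific problem

A domain folding on the ribosome co-populates an unfolded chain (U), partially
folded ribosome-associated intermediates (I1, I2) and the native fold (N).
With a single CF₃ reporter incorporated into the nascent chain, each state
contributes one ¹⁹F resonance, so a 1D spectrum is a superposition of up to
four Lorentzian lines — sharp (~25 Hz) for the mobile unfolded chain, very
broad (hundreds of Hz) for intermediates bound to the ~2.3 MDa particle.
Because interconversion is slow (k_ex ≲ 1 s⁻¹), peak integrals are directly
proportional to state concentrations, and populations measured across a
series of arrested constructs of increasing linker length map out the
co-translational folding transition:

- **Line-shape deconvolution** — nonlinear least squares over Lorentzian
  components in the frequency domain (`fit_lorentzians()`, `fit_states()`)
  or, by variable projection, in the time domain (`fit_time_domain()`), with
  the number of states chosen by a time-domain BIC (`select_n_states()`).
- **Uncertainties** — bootstrapping of residuals with refits from the
  original solution (`bootstrap_fit()`).
- **Thermodynamics** — ΔG_X–U = −RT ln(p_X/p_U) with detection-limit
  censoring into one-sided bounds (`delta_g()`), mutation ΔΔG (`ddg()`), and
  the free-energy landscape across linker lengths (`build_landscape()`).
- **Exchange kinetics** — Bloch–McConnell simulation and fitting of CEST
  profiles (`bm_cest()`, `fit_cest()`), rate upper bounds from flat profiles
  (`kex_upper_bound()`), and on-resonance R1ρ (`r1rho_rate()`, `fit_r1rho()`).
- **Sample integrity** — Stejskal–Tanner stimulated-echo diffusion fits and
  ribosome-attachment classification (`st_attenuation()`, `fit_D()`).
- **Synthetic data** — a generator for FIDs, linker-length series, CEST and
  diffusion datasets with known ground truth (`synth_fid()`,
  `synth_length_series()`, ...), so the entire chain is testable end to end.

## Worked example

Simulate a four-state RNC spectrum at a signal-to-noise ratio of 20, fit it,
and convert populations into free energies:

```r
library(fluorfold)

acq <- acq_params()                        # 470.4 MHz, 20 ppm / -62 ppm, 350 ms
con <- paper_like_construct()              # U, I1, I2, N at 0.25 each
fid <- synth_fid(con, acq, noise_spec(noise_sd_for_snr(con, acq, 20), seed = 1))

sp   <- estimate_noise(to_spectrum(fid, zero_fill_factor = 1), c(-54, -58))
fit  <- fit_states(sp, window = c(-60.5, -63.8))
boot <- bootstrap_fit(fit, B = 200, seed = 2)
pops <- populations_from_fit(fit, boot = boot)
pops
#> <population_set> total integral 0.001057, detection limit 0.050
#>   state fraction     sd   status bound residual
#> 1     U    0.234 0.0126 detected    NA       NA
#> 2    I1    0.284 0.0198 detected    NA       NA
#> 3    I2    0.244 0.0389 detected    NA       NA
#> 4     N    0.238 0.0283 detected    NA       NA

for (fe in delta_g(pops)) print(fe)
#> dG_I1-U = -0.114 +/- 0.061 kcal/mol
#> dG_I2-U = -0.024 +/- 0.121 kcal/mol
#> dG_N-U = -0.009 +/- 0.070 kcal/mol
```

The fitted fractions recover the generating populations (0.25 each) within
one to two bootstrap standard deviations, and the free energies are −RT log
population ratios against the unfolded state (RT = 0.5922 kcal/mol at 298 K),
so all four states sit within error of 0 kcal/mol of each other here. A state
whose resonance falls below the ~5% detection level would
instead appear as `below_limit`, and its row in `delta_g()` as a one-sided
bound. `run_folding_analysis()` chains the same steps over a whole
linker-length series and `write_report()` emits populations, peaks and the
ΔG landscape as TSV/JSON.

Model selection on the same data picks four states:

```r
select_n_states(fid, n_max = 5)$n_best
#> [1] 4
```

## Package layout

- `R/` — synthetic generator, processing, line-shape fitting and S3 methods,
  bootstrap, populations/thermodynamics, Bloch–McConnell kinetics, diffusion,
  pipeline orchestration, text IO.
- `tests/testthat/` — unit and property tests per module plus full-scale
  acceptance properties (`test-acceptance.R`).
- `vignettes/fluorfold-methods.Rmd` — the models, assumptions, parameter
  choices and limitations, in detail.
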