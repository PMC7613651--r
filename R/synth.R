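#' Specify one nascent-chain state
#'
#' A state is a single 19F resonance characterised by its chemical shift,
#' Lorentzian line-width and fractional population. The four canonical
#' nascent-chain states are U (unfolded, sharp, ~-61.8 ppm), I1 and I2
#' (ribosome-associated intermediates, broad) and N (native, ~-62.6 ppm).
#'
#' @param label state tag, one of `"U"`, `"I1"`, `"I2"`, `"N"` (other tags are
#'   allowed for generic use).
#' @param shift_ppm 19F chemical shift in ppm.
#' @param fwhm_hz full line-width at half maximum in Hz; must be positive.
#' @param population fractional population in `[0, 1]`.
#' @return An object of class `state_spec`.
#' @export
state_spec <- function(label, shift_ppm, fwhm_hz, population) {
  .assert(is.character(label) && length(label) == 1L, "label must be a string")
  .assert(.is_num1(shift_ppm), "shift_ppm must be a number")
  .assert(.is_num1(fwhm_hz) && fwhm_hz > 0, "fwhm_hz must be > 0")
  .assert(.is_num1(population) && population >= 0 && population <= 1,
          "population must lie in [0, 1]")
  structure(list(label = label, shift_ppm = shift_ppm, fwhm_hz = fwhm_hz,
                 population = population), class = "state_spec")
}

#' Specify a ribosome-nascent chain construct
#'
#' Bundles the states populated by one construct (one linker length and
#' mutation set) together with an overall signal scale proportional to the
#' sample concentration. Populations of the constituent states must sum to 1.
#'
#' @param name construct name, e.g. `"FLN5+34"`.
#' @param states list of [state_spec()] objects (non-empty).
#' @param linker_length residue count between domain and peptidyl transferase
#'   centre; non-negative integer.
#' @param mutations character vector of mutation tags (may be empty).
#' @param total_signal overall signal amplitude (arbitrary units, > 0);
#'   peak integrals scale linearly with it.
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(name, states, linker_length = 0L,
                           mutations = character(), total_signal = 1) {
  .assert(is.character(name) && length(name) == 1L, "name must be a string")
  .assert(is.list(states) && length(states) > 0 &&
            all(vapply(states, inherits, TRUE, "state_spec")),
          "states must be a non-empty list of state_spec objects")
  .assert(.is_num1(linker_length) && linker_length >= 0,
          "linker_length must be >= 0")
  .assert(.is_num1(total_signal) && total_signal > 0, "total_signal must be > 0")
  p <- vapply(states, `[[`, 0, "population")
  .assert(abs(sum(p) - 1) < 1e-9,
          "state populations must sum to 1 (got %.12f)", sum(p))
  structure(list(name = name, states = states,
                 linker_length = as.integer(linker_length),
                 mutations = mutations, total_signal = total_signal),
            class = "construct_spec")
}

#' Noise specification for synthetic data
#'
#' @param sd standard deviation of the additive Gaussian noise; for FIDs this
#'   is per real/imaginary component per time-domain point.
#' @param seed integer random seed; every stochastic generator takes its
#'   randomness exclusively from this seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0, seed = 1L) {
  .assert(.is_num1(sd) && sd >= 0, "sd must be >= 0")
  .assert(.is_num1(seed), "seed must be a single number")
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_spec")
}

# amplitude (time-domain, t=0) of each state: population * total_signal
.construct_amplitudes <- function(construct) {
  vapply(construct$states, `[[`, 0, "population") * construct$total_signal
}

#' Synthesize a free-induction decay for a construct
#'
#' The time-domain signal is the sum over states of exponentially damped
#' complex sinusoids,
#' \deqn{s(t) = \sum_k A_k \exp(i 2\pi \nu_k t - \pi \Gamma_k t),}
#' with amplitude \eqn{A_k} proportional to population times `total_signal`,
#' offset frequency \eqn{\nu_k = (\delta_k - \delta_{carrier}) \cdot \nu_F}
#' in Hz and \eqn{\Gamma_k} the full width at half maximum in Hz — the exact
#' time-domain counterpart of a sum of absorption Lorentzians. Independent
#' complex Gaussian noise (sd per component from `noise`) is added; the output
#' is deterministic given `noise$seed`.
#'
#' @param construct a [construct_spec()].
#' @param acq an [acq_params()]; every state shift must lie inside its window.
#' @param noise a [noise_spec()].
#' @return An object of class `fid` with attribute `"truth"` holding the
#'   generating construct.
#' @export
synth_fid <- function(construct, acq = acq_params(), noise = noise_spec()) {
  .assert(inherits(construct, "construct_spec"), "construct must be a construct_spec")
  .validate_acq(acq)
  .assert(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  .assert(acq$n_points > 0, "zero points requested")
  win <- .acq_window_ppm(acq)
  for (st in construct$states) {
    .assert(st$shift_ppm <= win[1] && st$shift_ppm >= win[2],
            "state %s at %.2f ppm lies outside the spectral window [%.2f, %.2f]",
            st$label, st$shift_ppm, win[2], win[1])
  }
  t <- (seq_len(acq$n_points) - 1) / acq$sweep_width_hz
  amps <- .construct_amplitudes(construct)
  s <- complex(real = numeric(acq$n_points), imaginary = numeric(acq$n_points))
  for (k in seq_along(construct$states)) {
    st <- construct$states[[k]]
    nu <- (st$shift_ppm - acq$carrier_ppm) * acq$spectrometer_freq_mhz
    s <- s + amps[k] * exp(complex(real = -pi * st$fwhm_hz * t,
                                   imaginary = 2 * pi * nu * t))
  }
  if (noise$sd > 0) {
    eps <- with_seed(noise$seed, {
      complex(real = stats::rnorm(acq$n_points, 0, noise$sd),
              imaginary = stats::rnorm(acq$n_points, 0, noise$sd))
    })
    s <- s + eps
  }
  out <- new_fid(s, acq)
  attr(out, "truth") <- construct
  out
}

#' Time-domain noise level giving a target spectral signal-to-noise ratio
#'
#' SNR is defined as the height of the tallest expected absorption peak
#' (after apodization with `lb_hz`) divided by the frequency-domain noise
#' standard deviation. White complex time-domain noise of sd \eqn{\sigma_t}
#' propagates to a real-part spectral sd of \eqn{\sigma_t \sqrt{N} / sw}.
#'
#' @param construct a [construct_spec()].
#' @param acq an [acq_params()].
#' @param snr target signal-to-noise ratio (> 0).
#' @param lb_hz line-broadening that will be applied during processing.
#' @return time-domain per-component noise sd.
#' @export
noise_sd_for_snr <- function(construct, acq = acq_params(), snr = 20, lb_hz = 10) {
  .assert(.is_num1(snr) && snr > 0, "snr must be > 0")
  amps <- .construct_amplitudes(construct)
  fw <- vapply(construct$states, `[[`, 0, "fwhm_hz") + lb_hz
  height <- max(amps / (pi * fw))       # peak height in intensity (per-Hz) units
  sigma_f <- height / snr
  sigma_f * acq$sweep_width_hz / sqrt(acq$n_points)
}

# ---- length series -----------------------------------------------------

#' Population-versus-linker-length scenario
#'
#' Parametric curves describing how the four state populations evolve with
#' linker length: logistic decay for U, logistic rise for N and Gaussian bumps
#' in linker length for the intermediates I1 and I2. Raw curve values below
#' `floor` are set to zero (states are genuinely absent at those lengths, not
#' just faint) and the remainder renormalised to sum to 1. The defaults place
#' the U decay midpoint just above 28 residues, the I1 bump at 31–34, the I2
#' bump near 47 and a monotone N rise — the qualitative co-translational
#' folding transition of an immunoglobulin-like domain. Folded and
#' intermediate states are gated to zero below `onset` residues (complete
#' emergence of the domain from the exit tunnel), so short linkers are purely
#' unfolded.
#'
#' @param lengths integer vector of linker lengths to generate.
#' @param u_mid,u_scale logistic midpoint/scale of the U decay.
#' @param n_mid,n_scale logistic midpoint/scale of the N rise.
#' @param i1_center,i1_width,i1_amp Gaussian bump parameters for I1.
#' @param i2_center,i2_width,i2_amp Gaussian bump parameters for I2.
#' @param shifts_ppm named shifts for U, I1, I2, N (ppm).
#' @param fwhm_hz named line-widths for U, I1, I2, N (Hz).
#' @param floor populations below this raw value are treated as absent.
#' @param total_signal per-construct signal scale.
#' @return An object of class `length_scenario`.
#' @export
length_scenario <- function(lengths = c(21L, 28L, 31L, 34L, 37L, 42L, 47L, 56L, 67L, 110L),
                            u_mid = 37, u_scale = 4,
                            n_mid = 46, n_scale = 7,
                            i1_center = 32.5, i1_width = 4, i1_amp = 0.45,
                            i2_center = 46, i2_width = 9, i2_amp = 0.6,
                            onset = 29,
                            shifts_ppm = c(U = -61.8, I1 = -61.9, I2 = -62.5, N = -62.6),
                            fwhm_hz = c(U = 25, I1 = 180, I2 = 220, N = 45),
                            floor = 0.02,
                            total_signal = 1) {
  .assert(length(lengths) > 0 && all(lengths >= 0), "lengths must be >= 0")
  .assert(all(c("U", "I1", "I2", "N") %in% names(shifts_ppm)) &&
            all(c("U", "I1", "I2", "N") %in% names(fwhm_hz)),
          "shifts_ppm and fwhm_hz must name U, I1, I2, N")
  structure(list(lengths = as.integer(lengths),
                 u_mid = u_mid, u_scale = u_scale,
                 n_mid = n_mid, n_scale = n_scale,
                 i1_center = i1_center, i1_width = i1_width, i1_amp = i1_amp,
                 i2_center = i2_center, i2_width = i2_width, i2_amp = i2_amp,
                 onset = onset,
                 shifts_ppm = shifts_ppm, fwhm_hz = fwhm_hz,
                 floor = floor, total_signal = total_signal),
            class = "length_scenario")
}

#' True state populations of a scenario at given linker lengths
#'
#' @param scenario a [length_scenario()].
#' @param lengths linker lengths (defaults to the scenario's own).
#' @return matrix with one row per length, columns U, I1, I2, N, rows sum to 1.
#' @export
scenario_populations <- function(scenario, lengths = scenario$lengths) {
  .assert(inherits(scenario, "length_scenario"), "scenario must be a length_scenario")
  L <- as.numeric(lengths)
  raw <- cbind(
    U  = 1 / (1 + exp((L - scenario$u_mid) / scenario$u_scale)),
    I1 = scenario$i1_amp * exp(-0.5 * ((L - scenario$i1_center) / scenario$i1_width)^2),
    I2 = scenario$i2_amp * exp(-0.5 * ((L - scenario$i2_center) / scenario$i2_width)^2),
    N  = 1 / (1 + exp(-(L - scenario$n_mid) / scenario$n_scale))
  )
  .assert(all(raw >= 0), "scenario curves produced negative populations")
  raw[L < scenario$onset, c("I1", "I2", "N")] <- 0
  raw[raw < scenario$floor] <- 0
  .assert(all(rowSums(raw) > 0), "scenario produced an all-absent length")
  p <- raw / rowSums(raw)
  rownames(p) <- as.character(lengths)
  p
}

#' Synthesize a linker-length series of FIDs
#'
#' One construct/FID pair per linker length, with populations following the
#' scenario curves (summing to 1 at every length). Seeds for the individual
#' FIDs are derived deterministically from `noise$seed`.
#'
#' @param scenario a [length_scenario()].
#' @param acq an [acq_params()].
#' @param noise a [noise_spec()]; `sd` applies to every FID.
#' @return list with one element per length, each a list
#'   `(construct, fid, linker_length)`.
#' @export
synth_length_series <- function(scenario = length_scenario(),
                                acq = acq_params(), noise = noise_spec()) {
  p <- scenario_populations(scenario)
  out <- vector("list", length(scenario$lengths))
  for (i in seq_along(scenario$lengths)) {
    L <- scenario$lengths[i]
    present <- names(which(p[i, ] > 0))
    states <- lapply(present, function(lab) {
      state_spec(lab, scenario$shifts_ppm[[lab]], scenario$fwhm_hz[[lab]], p[i, lab])
    })
    con <- construct_spec(sprintf("L%d", L), states, linker_length = L,
                          total_signal = scenario$total_signal)
    ns <- noise_spec(noise$sd, seed = noise$seed + i * 1000L)
    out[[i]] <- list(construct = con, fid = synth_fid(con, acq, ns),
                     linker_length = L)
  }
  out
}

# ---- CEST / diffusion datasets ----------------------------------------

#' Synthesize a noisy CEST dataset
#'
#' Delegates the saturation physics to [bm_cest()] and adds i.i.d. Gaussian
#' noise to the normalized intensities. Deterministic given `noise$seed`.
#'
#' @param model an [exchange_model()].
#' @param exp a [cest_experiment()].
#' @param noise a [noise_spec()]; `sd` is on the I/I0 scale.
#' @return A `cest_profile` (see [bm_cest()]) with `noise_sd` recorded.
#' @export
synth_cest_dataset <- function(model, exp, noise = noise_spec()) {
  prof <- bm_cest(model, exp)
  if (noise$sd > 0) {
    eps <- with_seed(noise$seed,
                     matrix(stats::rnorm(length(prof$intensity), 0, noise$sd),
                            nrow = nrow(prof$intensity)))
    prof$intensity <- prof$intensity + eps
  }
  prof$noise_sd <- noise$sd
  prof
}

#' Synthesize a stimulated-echo diffusion series
#'
#' Intensities follow the Stejskal-Tanner attenuation [st_attenuation()]
#' scaled by `reference_intensity`, plus Gaussian noise.
#'
#' @param D translational diffusion coefficient in m^2/s (> 0).
#' @param params a [diffusion_params()].
#' @param gradients gradient strengths in T/m (>= 0).
#' @param noise a [noise_spec()]; `sd` is absolute on the intensity scale.
#' @param reference_intensity intensity at zero gradient.
#' @return An object of class `diffusion_series` with fields
#'   `gradients_T_per_m`, `intensities`, `noise_sd`.
#' @export
synth_diffusion_dataset <- function(D, params = diffusion_params(),
                                    gradients = c(0.027, 0.513),
                                    noise = noise_spec(),
                                    reference_intensity = 1) {
  .assert(.is_num1(D) && D > 0, "D must be > 0")
  .assert(all(gradients >= 0), "gradients must be >= 0")
  I <- reference_intensity * vapply(gradients, function(g) st_attenuation(D, g, params), 0)
  if (noise$sd > 0) {
    I <- I + with_seed(noise$seed, stats::rnorm(length(I), 0, noise$sd))
  }
  structure(list(gradients_T_per_m = as.numeric(gradients),
                 intensities = I, noise_sd = noise$sd),
            class = "diffusion_series")
}
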