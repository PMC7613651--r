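# N-site slow chemical exchange: Bloch-McConnell simulation and fitting of
# CEST saturation profiles and on-resonance R1rho rates.

#' N-site chemical exchange model
#'
#' Sites are specified by label, equilibrium population, 19F shift and
#' relaxation rates. Exchange is parameterised either by per-pair rate
#' constants `kex` on a star topology through a hub state (default the first
#' site; for nascent chains, U), with the standard two-site convention
#' `k_ex = k_forward + k_backward` split according to the equilibrium
#' populations so detailed balance holds, or by a full `rates` generator
#' matrix (entry `[i, j]` = rate from j into i, columns summing to zero).
#'
#' @param populations numeric vector summing to 1.
#' @param shifts_ppm site shifts (ppm), same length.
#' @param R1_per_s,R2_per_s longitudinal/transverse relaxation rates (s^-1),
#'   recycled across sites.
#' @param kex pair exchange rate(s) hub<->site, s^-1: a scalar (all pairs) or
#'   one value per non-hub site. Ignored when `rates` is given.
#' @param rates optional full generator matrix (s^-1).
#' @param labels site labels.
#' @param hub index of the hub site for the star topology.
#' @param spectrometer_freq_mhz 19F frequency.
#' @return An object of class `exchange_model` with fields `sites` (data
#'   frame) and `K` (generator matrix, columns sum to 0, `K %*% p = 0`).
#' @export
exchange_model <- function(populations, shifts_ppm, R1_per_s = 1.5,
                           R2_per_s = 30, kex = 0, rates = NULL,
                           labels = NULL, hub = 1L,
                           spectrometer_freq_mhz = 470.4) {
  n <- length(populations)
  .assert(n >= 1 && length(shifts_ppm) == n, "populations and shifts_ppm lengths differ")
  .assert(abs(sum(populations) - 1) < 1e-9, "populations must sum to 1")
  .assert(all(populations > 0), "populations must be positive")
  labels <- labels %||% paste0("S", seq_len(n))
  R1 <- rep_len(R1_per_s, n); R2 <- rep_len(R2_per_s, n)
  if (is.null(rates)) {
    K <- matrix(0, n, n)
    if (n > 1 && any(kex > 0)) {
      others <- setdiff(seq_len(n), hub)
      kex <- rep_len(kex, length(others))
      for (m in seq_along(others)) {
        j <- others[m]
        ph <- populations[hub]; pj <- populations[j]
        k_hj <- kex[m] * pj / (ph + pj)   # hub -> site j
        k_jh <- kex[m] * ph / (ph + pj)   # site j -> hub
        K[j, hub] <- k_hj; K[hub, j] <- k_jh
      }
    }
    diag(K) <- -colSums(K)
  } else {
    K <- rates
    .assert(all(dim(K) == c(n, n)), "rates must be n x n")
    .assert(max(abs(colSums(K))) < 1e-9, "rate matrix columns must sum to 0")
  }
  # detailed balance: p_i k_{i->j} = p_j k_{j->i}, i.e. K[j,i] p_i = K[i,j] p_j
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      .assert(abs(K[j, i] * populations[i] - K[i, j] * populations[j]) < 1e-9,
              "detailed balance violated for pair (%d, %d)", i, j)
    }
  }
  structure(list(
    sites = data.frame(label = labels, population = populations,
                       shift_ppm = shifts_ppm, R1_per_s = R1, R2_per_s = R2),
    K = K, spectrometer_freq_mhz = spectrometer_freq_mhz),
    class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat(sprintf("<exchange_model> %d sites at %.1f MHz\n",
              nrow(x$sites), x$spectrometer_freq_mhz))
  print(x$sites, digits = 4)
  if (nrow(x$sites) > 1) {
    cat("exchange generator (s^-1):\n"); print(round(x$K, 5))
  }
  invisible(x)
}

#' CEST experiment settings
#'
#' @param b1_hz saturation field amplitude in Hz (paper-style default 15 Hz).
#' @param t_sat_s saturation duration in s (default 0.8).
#' @param offsets_ppm saturation frequencies.
#' @param reference_offset_ppm far off-resonance normalising offset
#'   (default -40 ppm).
#' @return An object of class `cest_experiment`.
#' @export
cest_experiment <- function(b1_hz = 15, t_sat_s = 0.8,
                            offsets_ppm = c(-62.2, -61.8, -62.6),
                            reference_offset_ppm = -40) {
  .assert(.is_num1(b1_hz) && b1_hz >= 0, "b1_hz must be >= 0")
  .assert(.is_num1(t_sat_s) && t_sat_s > 0, "t_sat_s must be > 0")
  structure(list(b1_hz = b1_hz, t_sat_s = t_sat_s,
                 offsets_ppm = as.numeric(offsets_ppm),
                 reference_offset_ppm = reference_offset_ppm),
            class = "cest_experiment")
}

#' Bloch-McConnell evolution matrix
#'
#' Assembles the homogeneous evolution matrix over the stacked
#' (Mx, My, Mz) components of all sites for continuous-wave irradiation of
#' amplitude `b1_hz` at `offset_ppm`, plus the inhomogeneous R1-recovery
#' vector. Per site: precession at \eqn{\Delta\omega_i = 2\pi(\delta_i -
#' offset)\nu_F}, nutation at \eqn{\omega_1 = 2\pi b_1} about x, transverse
#' decay R2 and longitudinal decay R1 toward \eqn{p_i M_0}; exchange couples
#' corresponding components between sites through the generator `K`.
#'
#' @param model an [exchange_model()].
#' @param b1_hz irradiation amplitude (Hz).
#' @param offset_ppm irradiation frequency (ppm).
#' @param include_recovery if `FALSE`, the R1 term decays to zero rather than
#'   to equilibrium (used for spin-lock decay rates).
#' @return list with `A` (3N x 3N matrix) and `b` (length-3N recovery vector).
#' @export
bm_matrix <- function(model, b1_hz, offset_ppm, include_recovery = TRUE) {
  .assert(inherits(model, "exchange_model"), "model must be an exchange_model")
  s <- model$sites
  n <- nrow(s)
  w1 <- 2 * pi * b1_hz
  A <- matrix(0, 3 * n, 3 * n)
  b <- numeric(3 * n)
  for (i in seq_len(n)) {
    dw <- 2 * pi * (s$shift_ppm[i] - offset_ppm) * model$spectrometer_freq_mhz
    ix <- 3 * (i - 1) + 1
    blk <- matrix(c(-s$R2_per_s[i],  dw,             0,
                    -dw,            -s$R2_per_s[i],  w1,
                     0,             -w1,            -s$R1_per_s[i]),
                  3, 3, byrow = TRUE)
    A[ix:(ix + 2), ix:(ix + 2)] <- blk
    if (include_recovery) b[ix + 2] <- s$R1_per_s[i] * s$population[i]
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (model$K[i, j] != 0) {
      ii <- 3 * (i - 1) + 1; jj <- 3 * (j - 1) + 1
      A[ii:(ii + 2), jj:(jj + 2)] <- A[ii:(ii + 2), jj:(jj + 2)] +
        diag(model$K[i, j], 3)
    }
  }
  list(A = A, b = b)
}

# propagate dM/dt = A M + b for time t from M0 (augmented matrix exponential)
.bm_expm_step <- function(A, b, M0, t) {
  n <- length(M0)
  Aug <- rbind(cbind(A, b), 0)
  out <- as.matrix(Matrix::expm(Aug * t)) %*% c(M0, 1)
  out[seq_len(n)]
}

#' Propagate magnetization under saturation
#'
#' Matrix-exponential solution of the (inhomogeneous) Bloch-McConnell system
#' from thermal equilibrium (Mz_i = p_i, transverse zero) for the saturation
#' duration.
#'
#' @param model an [exchange_model()].
#' @param exp a [cest_experiment()].
#' @param offset_ppm saturation frequency.
#' @return named numeric vector of per-site Mz at `t_sat`.
#' @export
bm_propagate <- function(model, exp, offset_ppm) {
  .assert(inherits(exp, "cest_experiment"), "exp must be a cest_experiment")
  .assert(exp$t_sat_s >= 0, "t_sat must be >= 0")
  s <- model$sites
  n <- nrow(s)
  M0 <- numeric(3 * n)
  M0[3 * seq_len(n)] <- s$population
  mats <- bm_matrix(model, exp$b1_hz, offset_ppm)
  M <- if (exp$t_sat_s == 0) M0 else .bm_expm_step(mats$A, mats$b, M0, exp$t_sat_s)
  stats::setNames(M[3 * seq_len(n)], s$label)
}

#' Simulate a CEST profile
#'
#' Per observed site, the normalized intensity is
#' `I/I0 = Mz(offset) / Mz(reference offset)`. The reference offset must lie
#' more than 10 ppm from every site (and is rejected within 2 ppm).
#'
#' @param model an [exchange_model()].
#' @param exp a [cest_experiment()].
#' @return An object of class `cest_profile`: `offsets_ppm`, `intensity`
#'   (matrix, offsets x sites), `model_sites`, `experiment`.
#' @export
bm_cest <- function(model, exp) {
  .assert(inherits(model, "exchange_model"), "model must be an exchange_model")
  .assert(inherits(exp, "cest_experiment"), "exp must be a cest_experiment")
  dmin <- min(abs(exp$reference_offset_ppm - model$sites$shift_ppm))
  .assert(dmin > 2, "reference offset within 2 ppm of a site")
  ref <- bm_propagate(model, exp, exp$reference_offset_ppm)
  I <- t(vapply(exp$offsets_ppm,
                function(o) bm_propagate(model, exp, o) / ref,
                numeric(nrow(model$sites))))
  if (nrow(model$sites) == 1L) I <- matrix(I, ncol = 1,
                                           dimnames = list(NULL, model$sites$label))
  structure(list(offsets_ppm = exp$offsets_ppm, intensity = I,
                 noise_sd = NULL, model_sites = model$sites, experiment = exp),
            class = "cest_profile")
}

#' @export
print.cest_profile <- function(x, ...) {
  cat(sprintf("<cest_profile> %d offsets x %d sites (B1 %.1f Hz, t_sat %.2f s)\n",
              length(x$offsets_ppm), ncol(x$intensity),
              x$experiment$b1_hz, x$experiment$t_sat_s))
  invisible(x)
}

# rebuild a model replacing all pair rates by kex (star topology retained)
.model_with_kex <- function(template, kex, R1 = NULL) {
  exchange_model(template$sites$population, template$sites$shift_ppm,
                 R1 %||% template$sites$R1_per_s, template$sites$R2_per_s,
                 kex = kex, labels = template$sites$label,
                 spectrometer_freq_mhz = template$spectrometer_freq_mhz)
}

#' Fit an exchange rate to CEST profiles
#'
#' Least-squares fit of the (global, star-topology) exchange rate constant —
#' and optionally a shared R1 — to one or more measured CEST profiles, with
#' populations, shifts and R2 fixed at the template values (from line-shape
#' fits). The error is covariance-based from the Jacobian at the solution.
#'
#' @param profiles a `cest_profile` or list of them.
#' @param model_template an [exchange_model()] supplying everything but the
#'   fitted parameters.
#' @param free parameters to fit: subset of `c("kex", "R1")`.
#' @param kex_init,kex_max search start and upper bound (s^-1).
#' @return An object of class `exchange_result`: `k_ex_per_s`, `err`, `kind =
#'   "point"`, plus the fit object.
#' @export
fit_cest <- function(profiles, model_template, free = "kex",
                     kex_init = 1, kex_max = 500) {
  if (inherits(profiles, "cest_profile")) profiles <- list(profiles)
  .assert(length(profiles) >= 1, "no profiles supplied")
  .assert("kex" %in% free, "kex must be among the free parameters")
  shifts <- model_template$sites$shift_ppm
  fw_ppm <- model_template$sites$R2_per_s / pi / model_template$spectrometer_freq_mhz
  informative <- FALSE
  for (pr in profiles) {
    for (o in pr$offsets_ppm) {
      if (any(abs(o - shifts) < 3 * pmax(fw_ppm, 0.02))) informative <- TRUE
    }
  }
  .assert(informative, "no offset lies within 3 line-widths of any site")
  obs <- unlist(lapply(profiles, function(p) as.numeric(p$intensity)))
  fit_r1 <- "R1" %in% free
  predict_all <- function(par) {
    m <- .model_with_kex(model_template, par[1],
                         R1 = if (fit_r1) par[2] else NULL)
    unlist(lapply(profiles, function(p) as.numeric(bm_cest(m, p$experiment)$intensity)))
  }
  par0 <- c(kex_init, if (fit_r1) mean(model_template$sites$R1_per_s))
  lo <- c(0, if (fit_r1) 1e-3); hi <- c(kex_max, if (fit_r1) 100)
  fit <- minpack.lm::nls.lm(par0, lo, hi, function(p) obs - predict_all(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200,
                                                                 ftol = 1e-12))
  dof <- max(length(obs) - length(par0), 1)
  sigma2 <- fit$deviance / dof
  cov <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  err <- if (!is.null(cov)) sqrt(pmax(diag(cov)[1], 0)) else NA_real_
  structure(list(k_ex_per_s = fit$par[1], err = err, kind = "point",
                 R1_per_s = if (fit_r1) fit$par[2] else NULL,
                 converged = fit$info %in% 1:4, fit = fit),
            class = "exchange_result")
}

#' @export
print.exchange_result <- function(x, ...) {
  if (x$kind == "point") {
    cat(sprintf("k_ex = %.3g +/- %.3g s^-1 (tau_ex = %.3g s)\n",
                x$k_ex_per_s, x$err, 1 / x$k_ex_per_s))
  } else {
    cat(sprintf("k_ex < %.3g s^-1 (tau_ex > %.3g s), %g-sigma bound\n",
                x$k_ex_per_s, 1 / x$k_ex_per_s, x$z %||% NA))
  }
  invisible(x)
}

#' Upper bound on the exchange rate from a flat CEST profile
#'
#' When saturating one site produces no significant dip at the others, the
#' data only bound the exchange rate: the bound is the largest `k_ex` whose
#' predicted maximal cross-site dip — in excess of the zero-exchange
#' prediction, so direct off-resonance saturation spillover does not count as
#' transfer — stays within `z` times the profile noise. Found by monotone
#' root bisection on the forward Bloch-McConnell model.
#'
#' @param profile a `cest_profile` (observed; used for its offsets and to
#'   verify no significant dip is present).
#' @param model_template an [exchange_model()].
#' @param noise_sd noise sd of the normalized intensities.
#' @param z significance threshold in noise units (default 2).
#' @return An `exchange_result` with `kind = "upper_bound"`.
#' @export
kex_upper_bound <- function(profile, model_template, noise_sd, z = 2) {
  .assert(inherits(profile, "cest_profile"), "profile must be a cest_profile")
  .assert(.is_num1(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  target <- z * noise_sd
  shifts <- model_template$sites$shift_ppm
  # zero-exchange baseline: direct saturation spillover is not transfer
  base <- bm_cest(.model_with_kex(model_template, 0), profile$experiment)$intensity
  obs_dip <- .max_cross_dip(base - profile$intensity,
                            profile$offsets_ppm, shifts)
  .assert(obs_dip <= target + 1e-12,
          "significant cross-site dip present (%.3f > %.3f); use fit_cest",
          obs_dip, target)
  if (target <= 0) {
    return(structure(list(k_ex_per_s = 0, err = NA_real_, kind = "upper_bound",
                          z = z), class = "exchange_result"))
  }
  dip_at <- function(k) {
    m <- .model_with_kex(model_template, k)
    I <- bm_cest(m, profile$experiment)$intensity
    .max_cross_dip(base - I, profile$experiment$offsets_ppm, shifts)
  }
  hi <- 1
  while (dip_at(hi) < target && hi < 1e4) hi <- hi * 2
  if (hi >= 1e4) k <- 1e4
  else k <- stats::uniroot(function(k) dip_at(k) - target, c(0, hi),
                           tol = 1e-4)$root
  structure(list(k_ex_per_s = k, err = NA_real_, kind = "upper_bound", z = z),
            class = "exchange_result")
}

# largest excess dip of site i when the offset nearest site j != i is
# irradiated; `dipmat` is (baseline - intensity) over offsets x sites
.max_cross_dip <- function(dipmat, offsets, shifts) {
  dip <- 0
  for (j in seq_along(shifts)) {
    io <- which.min(abs(offsets - shifts[j]))
    if (abs(offsets[io] - shifts[j]) > 0.2) next  # site j not irradiated
    for (i in seq_along(shifts)) {
      if (i == j) next
      dip <- max(dip, dipmat[io, i])
    }
  }
  dip
}

# ---- R1rho ---------------------------------------------------------------

#' R1rho experiment settings
#'
#' @param spinlock_hz spin-lock field amplitude in Hz (> 0; paper-style
#'   default 7500 Hz).
#' @param durations_s spin-lock durations.
#' @param carrier_ppm spin-lock carrier position.
#' @return An object of class `r1rho_experiment`.
#' @export
r1rho_experiment <- function(spinlock_hz = 7500,
                             durations_s = c(0.01, 0.05, 0.1, 0.2, 0.4),
                             carrier_ppm = -62.2) {
  .assert(.is_num1(spinlock_hz) && spinlock_hz > 0, "spinlock_hz must be > 0")
  structure(list(spinlock_hz = spinlock_hz, durations_s = durations_s,
                 carrier_ppm = carrier_ppm), class = "r1rho_experiment")
}

#' On-resonance rotating-frame relaxation rate
#'
#' Two routes are exposed. `closed_form` (two-site models only) is the
#' on-resonance slow-exchange expression
#' \deqn{R_{1\rho} = \bar{R}_2 + \frac{p_a p_b \Delta\omega^2 k_{ex}}
#'   {k_{ex}^2 + \Delta\omega^2 + \omega_1^2},}
#' with population-averaged \eqn{\bar{R}_2}. `numeric` extracts the decay rate
#' of the observed site's spin-locked magnetization from the
#' eigendecomposition of the spin-locked evolution matrix, as the
#' amplitude-weighted rate of the non-oscillatory decay modes (the rate a
#' mono-exponential fit of the decay measures).
#'
#' @param model an [exchange_model()].
#' @param exp an [r1rho_experiment()]; the carrier must lie on resonance with
#'   the observed site within `tol_ppm`.
#' @param observed_site index of the observed site (default the most
#'   populated).
#' @param tol_ppm tolerated carrier offset from the observed site.
#' @return list with `numeric` (s^-1), `closed_form` (s^-1 or NA for N > 2)
#'   and `R2_bar`.
#' @export
r1rho_rate <- function(model, exp, observed_site = NULL, tol_ppm = 0.05) {
  .assert(inherits(model, "exchange_model"), "model must be an exchange_model")
  .assert(inherits(exp, "r1rho_experiment"), "exp must be an r1rho_experiment")
  s <- model$sites
  n <- nrow(s)
  observed_site <- observed_site %||% which.max(s$population)
  .assert(abs(exp$carrier_ppm - s$shift_ppm[observed_site]) <= tol_ppm,
          "carrier is %.3f ppm off resonance from the observed site (tol %.3f)",
          abs(exp$carrier_ppm - s$shift_ppm[observed_site]), tol_ppm)
  mats <- bm_matrix(model, exp$spinlock_hz, exp$carrier_ppm,
                    include_recovery = FALSE)
  M0 <- numeric(3 * n)
  M0[3 * (seq_len(n) - 1) + 1] <- s$population  # locked along x
  eg <- eigen(mats$A)
  co <- solve(eg$vectors, M0)
  # decay of the observed site's x-magnetization: amplitude-weighted rate of
  # the non-oscillatory modes (the rate a mono-exponential fit measures)
  u <- numeric(3 * n); u[3 * (observed_site - 1) + 1] <- 1
  w <- as.vector(t(u) %*% eg$vectors) * co
  keep <- abs(Im(eg$values)) < 1e-3 * (abs(Re(eg$values)) + 2 * pi * exp$spinlock_hz)
  keep <- keep & Mod(w) > 1e-9 * sum(Mod(w))
  if (!any(keep)) keep <- rep(TRUE, length(w))
  num <- sum(Mod(w[keep]) * (-Re(eg$values[keep]))) / sum(Mod(w[keep]))
  closed <- NA_real_
  R2bar <- sum(s$population * s$R2_per_s)
  if (n == 2) {
    dw <- 2 * pi * abs(diff(s$shift_ppm)) * model$spectrometer_freq_mhz
    kex <- model$K[1, 2] + model$K[2, 1]
    w1 <- 2 * pi * exp$spinlock_hz
    closed <- R2bar + prod(s$population) * dw^2 * kex / (kex^2 + dw^2 + w1^2)
  }
  list(numeric = num, closed_form = closed, R2_bar = R2bar)
}

#' Fit a mono-exponential R1rho decay
#'
#' @param durations_s spin-lock durations (>= 3 values).
#' @param intensities observed intensities (positive, decaying).
#' @return list with `rate_per_s`, `sd`, `I0`.
#' @export
fit_r1rho <- function(durations_s, intensities) {
  .assert(length(durations_s) >= 3, "need >= 3 spin-lock durations")
  .assert(length(intensities) == length(durations_s), "length mismatch")
  .assert(all(intensities > 0), "intensities must be positive")
  sl <- unname(stats::coef(stats::lm(log(intensities) ~ durations_s))[2])
  .assert(sl < 0, "series does not decay; R1rho undefined")
  fit <- minpack.lm::nls.lm(c(max(intensities), -sl),
                            fn = function(p) intensities - p[1] * exp(-p[2] * durations_s),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  dof <- max(length(intensities) - 2, 1)
  cov <- tryCatch(fit$deviance / dof * solve(fit$hessian), error = function(e) NULL)
  list(rate_per_s = fit$par[2],
       sd = if (!is.null(cov)) sqrt(max(diag(cov)[2], 0)) else NA_real_,
       I0 = fit$par[1])
}
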