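# Lorentzian deconvolution, time-domain fits, model selection, assignment

test_that("initial peak picking finds resolved peaks and pads by splitting", {
  acq <- small_acq()
  con <- construct_spec("two", list(state_spec("U", -61.8, 25, 0.5),
                                    state_spec("N", -62.6, 45, 0.5)))
  sp <- to_spectrum(synth_fid(con, acq))
  g2 <- pick_initial_peaks(sp, 2)
  expect_equal(sort(g2$center_ppm), sort(c(-61.8, -62.6)), tolerance = 0.05 / 62)
  g1 <- pick_initial_peaks(sp, 1)
  expect_equal(g1$center_ppm, sp$ppm[which.max(sp$intensity)])
  g4 <- pick_initial_peaks(sp, 4)
  expect_equal(nrow(g4), 4)
  flat <- new_spectrum1d(sp$ppm, rep(1, length(sp$ppm)))
  expect_error(pick_initial_peaks(flat, 2), "flat")
  expect_error(pick_initial_peaks(sp, 7), "1..6")
})

test_that("noiseless single-Lorentzian fit is exact to 1e-6 relative", {
  acq <- small_acq()
  sp <- synth_spectrum(single_u(), acq)
  fit <- fit_lorentzians(sp, 1)
  expect_true(fit$converged)
  expect_equal(fit$peaks$center_ppm, -61.8, tolerance = 1e-6)
  expect_equal(fit$peaks$fwhm_hz, 25, tolerance = 1e-6)
  expect_equal(fit$peaks$integral, 1 / (2 * acq$spectrometer_freq_mhz),
               tolerance = 1e-6)
})

test_that("fit result invariants hold: residual length, rss, peak order", {
  acq <- small_acq()
  sp <- to_spectrum(synth_fid(four_state(), acq, noise_spec(1e-3, 1)))
  fit <- fit_lorentzians(sp, 4, window = c(-60.8, -63.6))
  expect_length(fit$residuals, length(fit$data$ppm))
  expect_equal(fit$rss, sum(fit$residuals^2), tolerance = 1e-12)
  expect_true(all(diff(fit$peaks$center_ppm) < 0))
  expect_error(fit_lorentzians(sp, 7), "6")
})

test_that("residuals of a correct-n fit are white", {
  acq <- small_acq()
  sd_t <- noise_sd_for_snr(single_u(), acq, 30, lb_hz = 0)
  ac1 <- vapply(1:5, function(s) {
    sp <- to_spectrum(synth_fid(single_u(), acq, noise_spec(sd_t, s)), 1)
    fit <- fit_lorentzians(sp, 1, window = c(-60.8, -63.0))
    r <- fit$residuals
    abs(stats::cor(r[-1], r[-length(r)]))
  }, 0)
  expect_lt(mean(ac1), 3 / sqrt(length(
    to_spectrum(synth_fid(single_u(), acq), 1)$ppm) * 0.22))
})

test_that("time- and frequency-domain fits agree on noiseless data", {
  acq <- small_acq()
  con <- four_state(c(0.4, 0.15, 0.2, 0.25))
  ftd <- fit_time_domain(synth_fid(con, acq), 4)
  ffd <- fit_lorentzians(synth_spectrum(con, acq), 4,
                         init = ftd$peaks[, c("center_ppm", "fwhm_hz", "integral")])
  expect_true(ftd$converged && ffd$converged)
  for (col in c("center_ppm", "fwhm_hz", "integral")) {
    expect_equal(ftd$peaks[[col]], ffd$peaks[[col]], tolerance = 1e-6)
  }
  expect_error(fit_time_domain(synth_fid(con, acq), 0), ">= 1")
})

test_that("BIC model selection recovers the true component count", {
  acq <- small_acq()
  sd1 <- noise_sd_for_snr(single_u(), acq, 50)
  fid1 <- synth_fid(single_u(), acq, noise_spec(sd1, 1))
  expect_equal(select_n_states(fid1, 3)$n_best, 1)
  # two states merged at identical shift: parsimony selects one
  merged <- construct_spec("m", list(state_spec("A", -61.8, 25, 0.5),
                                     state_spec("B", -61.8, 25, 0.5)))
  fidm <- synth_fid(merged, acq, noise_spec(sd1, 2))
  expect_equal(select_n_states(fidm, 3)$n_best, 1)
  # four well-populated states at good SNR
  con <- four_state()
  sd4 <- noise_sd_for_snr(con, acq, 30)
  fid4 <- synth_fid(con, acq, noise_spec(sd4, 3))
  expect_equal(select_n_states(fid4, 5)$n_best, 4)
})

test_that("fit_lineshape dispatches on spectra and FIDs", {
  acq <- small_acq()
  con <- four_state()
  sd4 <- noise_sd_for_snr(con, acq, 30)
  fid <- synth_fid(con, acq, noise_spec(sd4, 5))
  f1 <- fit_lineshape(to_spectrum(fid), 4, window = c(-60.8, -63.6))
  expect_s3_class(f1, "lineshape_fit")
  expect_identical(f1$domain, "frequency")
  f2 <- fit_lineshape(fid, n = "auto", n_max = 4)
  expect_identical(f2$domain, "time")
  expect_equal(f2$n_states, 4)
  expect_error(fit_lineshape(to_spectrum(fid), "auto"), "numeric")
  # methods are coherent
  expect_length(coef(f1), 12)
  expect_equal(length(fitted(f1)), length(f1$data$ppm))
  expect_equal(residuals(f1), f1$data$intensity - fitted(f1), tolerance = 1e-12)
  s <- summary(f1)
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
})

test_that("state assignment follows the narrow/broad x shift-proximity rule", {
  mkfit <- function(centers, widths) {
    pk <- data.frame(center_ppm = centers, fwhm_hz = widths,
                     integral = rep(1, length(centers)))
    structure(list(peaks = pk, residuals = 0, rss = 0,
                   n_states = length(centers), converged = TRUE,
                   domain = "frequency", sfrq = 470.4),
              class = "lineshape_fit")
  }
  f1 <- assign_states(mkfit(c(-61.8, -62.6), c(25, 45)))
  expect_equal(f1$peaks$label, c("U", "N"))
  f2 <- assign_states(mkfit(c(-61.9, -62.5), c(200, 220)))
  expect_equal(f2$peaks$label, c("I1", "I2"))
  f3 <- assign_states(mkfit(-61.8, 25))
  expect_equal(f3$peaks$label, "U")
  expect_error(assign_states(mkfit(c(-61.8, -61.82), c(25, 30))),
               "same narrow label|claim the narrow")
})

test_that("populations follow integral ratios with detection-limit censoring", {
  acq <- small_acq()
  sp <- synth_spectrum(four_state(), acq)
  sp$noise_sd <- 1e-9
  fit <- assign_states(fit_lorentzians(sp, 4, window = c(-60.8, -63.6)))
  pops <- populations_from_fit(fit)
  expect_equal(pops$table$fraction, rep(0.25, 4), tolerance = 1e-6)
  expect_true(all(pops$table$status == "detected"))
  # 3:1 areas give exact 0.75 / 0.25
  con <- construct_spec("ratio", list(state_spec("U", -61.8, 25, 0.75),
                                      state_spec("N", -62.6, 45, 0.25)))
  sp2 <- synth_spectrum(con, acq)
  sp2$noise_sd <- 1e-4   # noise-implied limit ~9%, so the 5% cap applies
  fit2 <- assign_states(fit_lorentzians(sp2, 2, window = c(-60.8, -63.6)))
  pops2 <- populations_from_fit(fit2, expected_states = c("U", "N"))
  expect_equal(sort(pops2$table$fraction), c(0.25, 0.75), tolerance = 1e-6)
  # expected state N absent: below_limit with the capped 5% bound
  pops3 <- populations_from_fit(fit2, expected_states = c("U", "N", "I1"))
  i1 <- pops3$table[pops3$table$state == "I1", ]
  expect_identical(i1$status, "below_limit")
  expect_equal(i1$bound, 0.05)
  # detected fractions plus residual allowances sum to 1
  tot <- sum(pops3$table$fraction, na.rm = TRUE) +
    sum(pops3$table$residual, na.rm = TRUE)
  expect_equal(tot, 1, tolerance = 1e-9)
  # zero total integral rejected
  fit0 <- fit2; fit0$peaks$integral <- 0
  expect_error(populations_from_fit(fit0), "zero total")
})

test_that("templated state fit quantifies a paper-like mixture without labels swapping", {
  acq <- small_acq()
  con <- four_state(c(0.45, 0.28, 0.17, 0.10))
  sd_t <- noise_sd_for_snr(con, acq, 40)
  maxerr <- vapply(1:6, function(s) {
    sp <- to_spectrum(synth_fid(con, acq, noise_spec(sd_t, s)), 1)
    fit <- fit_states(sp, window = c(-60.8, -63.6))
    fr <- stats::setNames(fit$peaks$integral / sum(fit$peaks$integral),
                          fit$peaks$label)
    expect_setequal(fit$peaks$label, c("U", "I1", "I2", "N"))
    max(abs(fr[c("U", "I1", "I2", "N")] - c(0.45, 0.28, 0.17, 0.10)))
  }, 0)
  expect_lt(median(maxerr), 0.06)
})

test_that("population recovery error shrinks as SNR doubles", {
  acq <- small_acq()
  con <- four_state()
  err_at <- function(snr) {
    e <- vapply(1:6, function(s) {
      sd_t <- noise_sd_for_snr(con, acq, snr)
      sp <- to_spectrum(synth_fid(con, acq, noise_spec(sd_t, s)), 1)
      fit <- fit_states(sp, window = c(-60.8, -63.6))
      fr <- stats::setNames(fit$peaks$integral / sum(fit$peaks$integral),
                            fit$peaks$label)
      sqrt(mean((fr[c("U", "I1", "I2", "N")] - 0.25)^2))
    }, 0)
    mean(e)
  }
  errs <- vapply(c(5, 20, 80), err_at, 0)
  expect_true(all(diff(errs) < 0))
})
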