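# spectral processing: apodization, Fourier transform, baseline, noise

test_that("apodization is the identity at lb = 0 and rejects negative lb", {
  fid <- synth_fid(single_u(), small_acq(), noise_spec(0.01, 1))
  expect_identical(apodize(fid, 0)$samples, fid$samples)
  expect_error(apodize(fid, -1), ">= 0")
})

test_that("apodization adds exactly lb to the fitted Lorentzian width", {
  acq <- small_acq()
  fid <- synth_fid(single_u(), acq, noise_spec(0))
  for (lb in c(5, 10)) {
    fit <- fit_lorentzians(to_spectrum(apodize(fid, lb)), 1,
                           window = c(-61, -62.6))
    expect_equal(fit$peaks$fwhm_hz, 25 + lb, tolerance = 5e-4)
  }
})

test_that("apodization is linear", {
  acq <- small_acq()
  x <- synth_fid(single_u(), acq, noise_spec(0.01, 1))
  y <- synth_fid(four_state(), acq, noise_spec(0.02, 2))
  z <- x; z$samples <- 2 * x$samples + 3 * y$samples
  lhs <- apodize(z, 12)$samples
  rhs <- 2 * apodize(x, 12)$samples + 3 * apodize(y, 12)$samples
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("ppm axis endpoints equal carrier +/- sw/(2*sfrq) exactly", {
  acq <- small_acq()
  sp <- to_spectrum(synth_fid(single_u(), acq), zero_fill_factor = 2)
  half <- acq$sweep_width_hz / (2 * acq$spectrometer_freq_mhz)
  expect_identical(sp$ppm[1], acq$carrier_ppm + half)
  expect_identical(sp$ppm[length(sp$ppm)], acq$carrier_ppm - half)
  expect_true(all(diff(sp$ppm) < 0))
})

test_that("Parseval's identity holds for the plain transform", {
  acq <- small_acq()
  fid <- synth_fid(four_state(), acq, noise_spec(0.01, 3))
  n <- acq$n_points
  s <- fid$samples
  S <- stats::fft(s)
  e_t <- sum(Mod(s)^2)
  e_f <- sum(Mod(S)^2) / n
  expect_equal(e_t, e_f, tolerance = 1e-9)
  # and the packaged transform preserves a noiseless Lorentzian's integral
  spL <- to_spectrum(synth_fid(single_u(), acq))
  dppm <- abs(diff(spL$ppm[1:2]))
  expect_equal(sum(spL$intensity) * dppm,
               1 / (2 * acq$spectrometer_freq_mhz), tolerance = 1e-3)
})

test_that("two states 0.8 ppm apart give two maxima 0.8 ppm apart", {
  acq <- small_acq()
  con <- construct_spec("two", list(state_spec("U", -61.8, 25, 0.5),
                                    state_spec("X", -62.6, 25, 0.5)))
  sp <- to_spectrum(synth_fid(con, acq))
  sel <- sp$ppm < -61 & sp$ppm > -63
  y <- sp$intensity[sel]; x <- sp$ppm[sel]
  locmax <- which(diff(sign(diff(y))) < 0) + 1
  locmax <- locmax[order(y[locmax], decreasing = TRUE)][1:2]
  expect_equal(abs(diff(x[locmax])), 0.8,
               tolerance = 2 * abs(diff(sp$ppm[1:2])) / 0.8)
})

test_that("empty FIDs and bad zero-fill are rejected", {
  fid <- synth_fid(single_u(), small_acq())
  fid$samples <- complex(0)
  expect_error(to_spectrum(fid), "empty")
  expect_error(to_spectrum(synth_fid(single_u(), small_acq()), 0.5), ">= 1")
})

test_that("baseline correction removes offsets and broad backgrounds", {
  acq <- small_acq()
  sp <- to_spectrum(synth_fid(single_u(), acq))
  sig <- list(c(-61.0, -62.6))
  # flat zero baseline: exact identity
  flat <- new_spectrum1d(sp$ppm, numeric(length(sp$ppm)), acq = acq)
  out0 <- baseline_correct(flat, sig)
  expect_equal(out0$intensity, flat$intensity, tolerance = 1e-9)
  # spectrum with no added baseline: correction is inert within tail leakage
  out <- baseline_correct(sp, sig)
  expect_lt(max(abs(out$intensity - sp$intensity)), 2e-3 * max(sp$intensity))
  truth_area <- 1 / (2 * acq$spectrometer_freq_mhz)
  area <- function(s) {
    f <- fit_lorentzians(s, 1, window = c(-61.2, -62.4))
    f$peaks$integral
  }
  # constant offset is annihilated, peak integral preserved within 1%
  spc <- sp; spc$intensity <- sp$intensity + 0.05 * max(sp$intensity)
  corr <- baseline_correct(spc, sig)
  expect_equal(area(corr), truth_area, tolerance = 0.01)
  # broad instrument background: integral recovered within 2%
  spb <- add_instrument_background(sp, center_ppm = -61.5, fwhm_hz = 2500,
                                   area = 5 * truth_area)
  corrb <- baseline_correct(spb, sig)
  expect_equal(area(corrb), truth_area, tolerance = 0.02)
  # rolling-minimum alternative also removes a constant within noise
  corr2 <- baseline_correct(spc, sig, method = "rolling_min")
  quiet <- corr2$intensity[corr2$ppm < -58.2 & corr2$ppm > -59.8]
  expect_lt(abs(mean(quiet)), 0.01 * max(sp$intensity))
  expect_error(baseline_correct(sp, list(range(sp$ppm))), "whole axis")
})

test_that("noise estimation matches the analytic propagation of white noise", {
  acq <- small_acq()
  sp0 <- to_spectrum(synth_fid(single_u(), acq, noise_spec(0)))
  expect_lt(estimate_noise(sp0, QUIET)$noise_sd, 1e-4 * max(sp0$intensity))
  sd_t <- 0.02
  sigma_f <- sd_t * sqrt(acq$n_points) / acq$sweep_width_hz
  ests <- vapply(1:10, function(s) {
    sp <- to_spectrum(synth_fid(single_u(), acq, noise_spec(sd_t, s)), 1)
    estimate_noise(sp, QUIET)$noise_sd
  }, 0)
  expect_lt(abs(mean(ests) - sigma_f) / sigma_f, 0.15)
  # guarded preconditions
  sp <- to_spectrum(synth_fid(single_u(), acq, noise_spec(sd_t, 1)))
  expect_error(estimate_noise(sp, c(-61.3, -62.3),
                              peaks = data.frame(center_ppm = -61.8)),
               "peak centre")
  expect_error(estimate_noise(sp, c(-58.000, -58.001)), ">= 50")
})

test_that("transform of an apodized FID equals Lorentzian convolution broadening", {
  # equivalent statement checked analytically: a noiseless state of width G
  # processed with lb yields the exact Lorentzian of width G + lb
  acq <- small_acq()
  fid <- synth_fid(single_u(), acq, noise_spec(0))
  sp <- to_spectrum(apodize(fid, 15))
  sf <- acq$spectrometer_freq_mhz
  model <- (2 * (1 / (2 * sf)) / (pi * (40 / sf))) /
    (1 + 4 * ((sp$ppm - (-61.8)) / (40 / sf))^2)
  expect_lt(max(abs(sp$intensity - model)) / max(model), 1e-3)
})
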