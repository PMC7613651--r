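# synthetic-data generator: signal model, determinism, series structure

test_that("noiseless FID is the analytic damped-sinusoid sum", {
  acq <- small_acq()
  fid <- synth_fid(single_u(), acq, noise_spec(0))
  t <- (seq_len(acq$n_points) - 1) / acq$sweep_width_hz
  nu <- (-61.8 - acq$carrier_ppm) * acq$spectrometer_freq_mhz
  expected <- exp(complex(real = -pi * 25 * t, imaginary = 2 * pi * nu * t))
  expect_equal(fid$samples, expected, tolerance = 1e-12)
  # processed spectrum peaks at the state's shift
  sp <- to_spectrum(fid)
  expect_lt(abs(sp$ppm[which.max(sp$intensity)] - (-61.8)),
            1.5 * abs(diff(sp$ppm[1:2])))
})

test_that("first FID sample equals the amplitude sum (zero phase at t = 0)", {
  con <- four_state(c(0.1, 0.2, 0.3, 0.4))
  fid <- synth_fid(con, small_acq(), noise_spec(0))
  expect_equal(Re(fid$samples[1]), 1, tolerance = 1e-12)
  expect_equal(Im(fid$samples[1]), 0, tolerance = 1e-12)
})

test_that("states outside the spectral window and empty acquisitions are rejected", {
  con <- construct_spec("far", list(state_spec("X", -40, 25, 1)))
  expect_error(synth_fid(con, small_acq()), "outside the spectral window")
  expect_error(construct_spec("bad", list()), "non-empty")
  expect_error(construct_spec("bad", list(state_spec("U", -61.8, 25, 0.5))),
               "sum to 1")
})

test_that("identical seeds give bit-identical FIDs, different seeds differ", {
  con <- four_state()
  a <- synth_fid(con, small_acq(), noise_spec(0.01, 42))
  b <- synth_fid(con, small_acq(), noise_spec(0.01, 42))
  c <- synth_fid(con, small_acq(), noise_spec(0.01, 43))
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("total fitted integral is proportional to total_signal (dilution series)", {
  acq <- small_acq()
  scales <- seq(0.2, 2, length.out = 10)
  tot <- vapply(scales, function(s) {
    con <- paper_like_construct(total_signal = s)
    sp <- to_spectrum(synth_fid(con, acq))
    fit <- fit_states(sp, window = c(-60.8, -63.6))
    sum(fit$peaks$integral)
  }, 0)
  expect_equal(tot / tot[1], scales / scales[1], tolerance = 1e-3)
})

test_that("length series populations sum to 1 and follow the folding transition", {
  sc <- length_scenario()
  p <- scenario_populations(sc)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)
  expect_equal(unname(p["21", ]), c(1, 0, 0, 0))
  expect_equal(unname(p["110", "N"]), 1, tolerance = 1e-6)
  lens <- sc$lengths
  expect_true(lens[which.max(p[, "I1"])] %in% 31:34)
  expect_true(abs(lens[which.max(p[, "I2"])] - 47) <= 5)
  expect_true(all(diff(p[, "N"]) >= -1e-12))
  # U decays only after 28 residues
  expect_true(all(p[as.character(c(21, 28)), "U"] == 1))
  expect_true(all(diff(p[, "U"]) <= 1e-12))
})

test_that("a scenario producing negative populations is rejected", {
  sc <- length_scenario(i1_amp = -1)
  expect_error(scenario_populations(sc), "negative")
})

test_that("length series yields one FID per length with matching constructs", {
  sc <- length_scenario(lengths = c(21L, 34L, 110L))
  ser <- synth_length_series(sc, small_acq(), noise_spec(0))
  expect_length(ser, 3)
  expect_equal(vapply(ser, `[[`, 0L, "linker_length"), c(21L, 34L, 110L))
  p1 <- vapply(ser[[1]]$construct$states, `[[`, 0, "population")
  expect_equal(sum(p1), 1, tolerance = 1e-12)
})

test_that("CEST dataset is the Bloch-McConnell prediction plus seeded noise", {
  m <- exchange_model(c(0.6, 0.4), c(-61.8, -62.6), R1 = 1.5, R2 = 30,
                      kex = 3.6, labels = c("U", "N"))
  ex <- cest_experiment(15, 0.8, c(-61.8, -62.6), -40)
  clean <- synth_cest_dataset(m, ex, noise_spec(0))
  expect_equal(clean$intensity, bm_cest(m, ex)$intensity, tolerance = 1e-12)
  # b1 = 0: no saturation anywhere
  ex0 <- cest_experiment(0, 0.8, c(-61.8, -62.6), -40)
  flat <- synth_cest_dataset(m, ex0, noise_spec(0))
  expect_equal(as.numeric(flat$intensity), rep(1, 4), tolerance = 1e-9)
  # determinism
  n1 <- synth_cest_dataset(m, ex, noise_spec(0.01, 7))
  n2 <- synth_cest_dataset(m, ex, noise_spec(0.01, 7))
  expect_identical(n1$intensity, n2$intensity)
})

test_that("diffusion datasets follow Stejskal-Tanner attenuation", {
  ds <- synth_diffusion_dataset(1.8e-11, gradients = c(0, 0.027, 0.513),
                                noise = noise_spec(0))
  expect_equal(ds$intensities[1], 1)
  expect_equal(ds$intensities[3] / ds$intensities[2], 0.6232, tolerance = 1e-3)
  same <- synth_diffusion_dataset(1e-10, gradients = c(0.2, 0.2),
                                  noise = noise_spec(0))
  expect_equal(same$intensities[1], same$intensities[2])
  expect_error(synth_diffusion_dataset(-1e-11, gradients = 0.1), "D must be > 0")
})
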