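# Bloch-McConnell physics, CEST simulation/fitting, R1rho

two_site <- function(kex, p = c(0.6, 0.4), shifts = c(-61.8, -62.6),
                     R1 = 1.5, R2 = 30) {
  exchange_model(p, shifts, R1_per_s = R1, R2_per_s = R2, kex = kex,
                 labels = c("U", "N"))
}

test_that("exchange generator satisfies stationarity and detailed balance", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    p <- runif(n); p <- p / sum(p)
    m <- exchange_model(p, runif(n, -63, -61), kex = runif(1, 0.1, 10))
    expect_lt(max(abs(m$K %*% m$sites$population)), 1e-12)
    expect_equal(max(abs(colSums(m$K))), 0, tolerance = 1e-12)
  }
  bad <- matrix(c(-1, 1, 2, -2), 2, 2)  # violates detailed balance at p = (.6,.4)
  expect_error(exchange_model(c(0.6, 0.4), c(-61.8, -62.6), rates = bad),
               "detailed balance")
})

test_that("b1 = 0 decouples Mz from the transverse components", {
  m <- two_site(0)
  mats <- bm_matrix(m, 0, -62)
  z <- c(3, 6); xy <- c(1, 2, 4, 5)
  expect_true(all(mats$A[z, xy] == 0) && all(mats$A[xy, z] == 0))
})

test_that("evolution matrix eigenvalues have non-positive real parts", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:4, 1)
    p <- runif(n); p <- p / sum(p)
    m <- exchange_model(p, runif(n, -63, -61), R1 = runif(1, 0, 3),
                        R2 = runif(n, 5, 300), kex = runif(1, 0, 10))
    A <- bm_matrix(m, runif(1, 0, 50), runif(1, -64, -60))$A
    expect_lt(max(Re(eigen(A, only.values = TRUE)$values)), 1e-10)
  }
})

test_that("total Mz is conserved without relaxation or irradiation", {
  m <- exchange_model(c(0.5, 0.3, 0.2), c(-61.8, -62.2, -62.6),
                      R1 = 0, R2 = 0, kex = 5)
  mats <- bm_matrix(m, 0, -62)
  M0 <- numeric(9); M0[c(3, 6, 9)] <- c(0.2, 0.5, 0.3)  # non-equilibrium start
  Mt <- fluorfold:::.bm_expm_step(mats$A, mats$b, M0, 3)
  expect_equal(sum(Mt[c(3, 6, 9)]), 1, tolerance = 1e-12)
})

test_that("propagation matches an adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(43)
  worst <- 0
  for (i in 1:15) {
    n <- sample(2:3, 1)
    p <- runif(n); p <- p / sum(p)
    m <- exchange_model(p, -62 + runif(n, -0.5, 0.5), R1 = runif(1, 0, 3),
                        R2 = runif(n, 5, 200), kex = runif(1, 0, 10))
    mats <- bm_matrix(m, runif(1, 0, 30), -62 + runif(1, -0.7, 0.7))
    M0 <- numeric(3 * n); M0[3 * seq_len(n)] <- p
    Me <- fluorfold:::.bm_expm_step(mats$A, mats$b, M0, 0.8)
    f <- function(t, y, parms) list(mats$A %*% y + mats$b)
    Mo <- deSolve::ode(M0, c(0, 0.8), f, NULL, rtol = 1e-11, atol = 1e-13,
                       maxsteps = 200000)[2, -1]
    worst <- max(worst, max(abs(Me - Mo)))
  }
  expect_lt(worst, 1e-8)
})

test_that("propagation limits: t = 0 and b1 = 0 with R1 = 0 leave Mz alone", {
  m <- two_site(3, R1 = 0)
  ex0 <- cest_experiment(15, 0.8, -62, -40); ex0$t_sat_s <- 1e-12
  expect_equal(unname(bm_propagate(m, ex0, -61.8)), c(0.6, 0.4),
               tolerance = 1e-9)
  exb0 <- cest_experiment(0, 0.8, -62, -40)
  expect_equal(unname(bm_propagate(m, exb0, -61.8)), c(0.6, 0.4),
               tolerance = 1e-12)
})

test_that("on-resonance saturation empties a site; without exchange nothing transfers", {
  m0 <- two_site(0, R2 = 20)
  ex <- cest_experiment(25, 3, c(-61.8, -62.6), -40)
  mz <- bm_propagate(m0, ex, -61.8)
  expect_lt(mz[["U"]] / 0.6, 0.05)        # irradiated site saturated
  # no exchange: site N behaves exactly like an isolated single-site system
  # (any residual dip is direct spillover, not transfer)
  prof <- bm_cest(m0, ex)
  mN <- exchange_model(1, -62.6, R1_per_s = 1.5, R2_per_s = 20, labels = "N")
  profN <- bm_cest(mN, ex)
  expect_equal(prof$intensity[, "N"], profN$intensity[, "N"], tolerance = 1e-6)
  expect_error(bm_cest(m0, cest_experiment(15, 0.8, -62, -61)), "within 2 ppm")
})

test_that("slow exchange produces a measurable cross-site CEST dip", {
  m <- two_site(3.6, R2 = c(15, 25))
  ex <- cest_experiment(15, 0.8, c(-61.8, -62.6), -40)
  prof <- bm_cest(m, ex)
  expect_lt(prof$intensity[2, "U"], 0.95)  # saturating N dips U
  # b1 = 0 gives a flat profile
  flat <- bm_cest(m, cest_experiment(0, 0.8, c(-61.8, -62.6), -40))
  expect_equal(as.numeric(flat$intensity), rep(1, 4), tolerance = 1e-9)
})

test_that("CEST fitting recovers the exchange rate", {
  offs <- seq(-61.2, -63.2, by = -0.2)
  ex <- cest_experiment(15, 0.8, offs, -40)
  truth <- two_site(3.6, R2 = c(15, 25))
  clean <- synth_cest_dataset(truth, ex, noise_spec(0))
  r <- fit_cest(clean, two_site(1, R2 = c(15, 25)))
  expect_equal(r$k_ex_per_s, 3.6, tolerance = 1e-4)
  # zero-rate truth: estimate CI includes 0
  clean0 <- synth_cest_dataset(two_site(0, R2 = c(15, 25)), ex, noise_spec(0.005, 3))
  r0 <- fit_cest(clean0, two_site(1, R2 = c(15, 25)))
  expect_lt(r0$k_ex_per_s - 2 * r0$err, 0)
  # uninformative offsets rejected
  far <- cest_experiment(15, 0.8, c(-50, -55), -40)
  pf <- synth_cest_dataset(truth, far, noise_spec(0))
  expect_error(fit_cest(pf, truth), "offset")
})

test_that("kex upper bound shrinks with noise and rejects significant dips", {
  m0 <- exchange_model(c(0.5, 0.5), c(-61.8, -62.2), R1 = 1.4, R2 = 30, kex = 0)
  tpl <- exchange_model(c(0.5, 0.5), c(-61.8, -62.2), R1 = 1.4, R2 = 30, kex = 1)
  ex <- cest_experiment(15, 0.8, c(-61.8, -62.2), -40)
  flat <- synth_cest_dataset(m0, ex, noise_spec(0))
  b <- vapply(c(0.04, 0.02, 0.01, 0.002), function(sd)
    kex_upper_bound(flat, tpl, sd)$k_ex_per_s, 0)
  expect_true(all(diff(b) < 0))          # monotone in noise
  expect_lt(b[4], 0.05)                  # bound -> 0 with noise
  expect_identical(kex_upper_bound(flat, tpl, 0.02)$kind, "upper_bound")
  dip <- synth_cest_dataset(exchange_model(c(0.5, 0.5), c(-61.8, -62.2),
                                           R1 = 1.4, R2 = 30, kex = 8),
                            ex, noise_spec(0))
  expect_error(kex_upper_bound(dip, tpl, 0.01), "significant")
})

test_that("closed-form on-resonance R1rho matches the numeric rate", {
  set.seed(44)
  worst <- 0
  for (i in 1:40) {
    p <- runif(1, 0.6, 0.95)
    m <- exchange_model(c(p, 1 - p), c(-62.2, -62.2 - runif(1, 0.3, 1)),
                        R1 = 0, R2 = runif(1, 5, 80), kex = runif(1, 0.5, 5))
    r <- r1rho_rate(m, r1rho_experiment(runif(1, 500, 2000),
                                        carrier_ppm = -62.2),
                    observed_site = 1)
    worst <- max(worst, abs(r$numeric - r$closed_form) / r$closed_form)
  }
  expect_lt(worst, 0.02)
  # limits: no exchange and infinite spin-lock both give R2
  m0 <- exchange_model(c(0.7, 0.3), c(-62.2, -62.6), R1 = 0, R2 = 22, kex = 0)
  expect_equal(r1rho_rate(m0, r1rho_experiment(7500, carrier_ppm = -62.2),
                          observed_site = 1)$numeric, 22, tolerance = 1e-9)
  m2 <- exchange_model(c(0.7, 0.3), c(-62.2, -62.6), R1 = 0, R2 = 22, kex = 2)
  expect_equal(r1rho_rate(m2, r1rho_experiment(5e5, carrier_ppm = -62.2),
                          observed_site = 1)$numeric, 22, tolerance = 1e-4)
  expect_error(r1rho_rate(m2, r1rho_experiment(7500, carrier_ppm = -61.0),
                          observed_site = 1), "off resonance")
})

test_that("R1rho decay fitting recovers rates and guards inputs", {
  ts <- c(0.01, 0.03, 0.06, 0.1, 0.2)
  I <- 2.5 * exp(-100 * ts)
  f <- fit_r1rho(ts, I)
  expect_equal(f$rate_per_s, 100, tolerance = 1e-9)
  # noisy recovery within 10% on average
  set.seed(45)
  rates <- vapply(1:20, function(s) {
    fit_r1rho(ts, I * (1 + rnorm(5, 0, 0.02)))$rate_per_s
  }, 0)
  expect_lt(abs(mean(rates) - 100) / 100, 0.1)
  expect_error(fit_r1rho(ts[1:2], I[1:2]), ">= 3")
  expect_error(fit_r1rho(ts, rev(I)), "decay")
})
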