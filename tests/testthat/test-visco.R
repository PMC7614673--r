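# Dynamic viscoelastic sensing: mean strain, amplitudes, calibration fits,
# time constant, loss modulus, full pipeline.

test_that("mean interface strain integrates the central window", {
  L <- 6.5e-3
  s <- seq(0, L, length.out = 101)
  expect_equal(mean_interface_strain(s, rep(0.1, 101), L), 0.1)
  expect_equal(mean_interface_strain(s, s / L, L), 0.5, tolerance = 1e-9)
  # against a fine-grid quadrature oracle
  f <- function(s) 0.05 * sin(2 * pi * s / L) + 0.02 * (s / L)^2
  sf <- seq(0.3 * L, 0.7 * L, length.out = 20001)
  oracle <- trapz(sf, f(sf)) / (0.4 * L)
  coarse <- mean_interface_strain(seq(0, L, length.out = 65),
                                  f(seq(0, L, length.out = 65)), L)
  expect_rel(coarse, oracle, 0.005)
  expect_error(mean_interface_strain(seq(0, 0.5 * L, length.out = 20),
                                     rep(1, 20), L),
               class = "magsense_domain_error")
})

test_that("amplitude extraction is exact on clean cycles, robust to noise", {
  tt <- seq(0, 4, by = 0.01)
  # phase-bin averaging biases a pure sinusoid down by < 1% (worst case:
  # peak on a bin edge)
  expect_equal(amplitude_of(tt, 0.19 * sin(2 * pi * tt), 1), 0.19,
               tolerance = 1e-2)
  expect_equal(amplitude_of(tt, rep(0.3, length(tt)), 1), 0)
  expect_error(amplitude_of(seq(0, 1.5, by = 0.01),
                            sin(2 * pi * seq(0, 1.5, by = 0.01)), 1),
               class = "magsense_insufficient_data")
  # 5% white noise over 10 cycles: within 2% after cycle folding
  set.seed(101)
  t10 <- seq(0, 10, by = 0.02)
  y <- 0.2 * sin(2 * pi * t10) + rnorm(length(t10), 0, 0.01)
  expect_rel(amplitude_of(t10, y, 1), 0.2, 0.02)
})

test_that("power-law calibration fit recovers the generating constants", {
  Ep <- c(1.9e3, 3.2e3, 6.2e3, 12e3, 25e3, 51.2e3)
  amp <- 54.128 * Ep^(-1.067)
  cal <- fit_calibration(Ep, amp)
  expect_rel(cal$k, 54.128, 1e-4)
  expect_rel(cal$a, -1.067, 1e-4)

  # two points: exact interpolating power law
  cal2 <- fit_calibration(c(2e3, 20e3), c(0.03, 0.002))
  pred <- cal2$k * c(2e3, 20e3)^cal2$a
  expect_equal(pred, c(0.03, 0.002), tolerance = 1e-10)

  # a = -1 with 3% noise, n = 8: exponent within 0.05
  set.seed(11)
  Ep8 <- exp(seq(log(2e3), log(50e3), length.out = 8))
  amp8 <- 54 * Ep8^(-1) * (1 + rnorm(8, 0, 0.03))
  expect_lt(abs(fit_calibration(Ep8, amp8)$a - (-1)), 0.05)

  expect_error(fit_calibration(c(2e3, 2e3), c(1, 1)),
               class = "magsense_domain_error")
  expect_error(fit_calibration(c(-1, 2e3), c(1, 1)),
               class = "magsense_domain_error")
})

test_that("storage modulus inversion is the exact inverse of the law", {
  cal <- visco_calibration()
  # unit exponent: closed form E' = k * By / amplitude
  cal1 <- visco_calibration(a = -1)
  expect_rel(estimate_storage_modulus(0.1, 20, cal1),
             cal1$k * 20 / 0.1, 1e-12)
  # round trip at 10 kPa
  amp <- cal$k * 1e4^cal$a * 20
  expect_rel(estimate_storage_modulus(amp, 20, cal), 1e4, 1e-10)
  expect_error(estimate_storage_modulus(-0.1, 20, cal),
               class = "magsense_domain_error")
})

test_that("time-constant fit handles clean, flat and printed data", {
  f <- c(0.1, 0.5, 1, 2, 5, 10, 15)
  A <- 0.2 / sqrt(1 + (2 * pi * f * 0.1)^2)
  expect_rel(fit_time_constant(f, A)$tau_s, 0.1, 0.01)

  expect_warning(ft0 <- fit_time_constant(f, rep(0.2, 7)),
                 class = "magsense_fit_degenerate")
  expect_equal(ft0$tau_s, 0)

  # two printed sweep points: closed-form two-point solve gives ~0.0327 s
  ft2 <- fit_time_constant(c(1.9, 14.2), c(0.23, 0.08))
  expect_equal(ft2$tau_s, 0.0327, tolerance = 0.01)
})

test_that("loss modulus follows E'' = k_tau E' / tau", {
  cal <- visco_calibration()
  expect_equal(estimate_loss_modulus(4e3, cal$k_tau, cal)$E_dprime_Pa, 4e3)
  # direct evaluation: E' = 6.5 kPa, tau = 0.2282 s -> ~2.0 kPa
  expect_rel(estimate_loss_modulus(6.5e3, 0.2282, cal)$E_dprime_Pa,
             0.0703 * 6500 / 0.2282, 1e-12)
  expect_equal(round(estimate_loss_modulus(6.5e3, 0.2282, cal)$E_dprime_Pa
                     / 1e3, 1), 2.0)
  el <- estimate_loss_modulus(4e3, 0, cal)
  expect_true(el$purely_elastic)
  expect_equal(el$E_dprime_Pa, 0)
})

test_that("full pipeline recovers synthetic moduli end to end", {
  sc <- synthetic_scenario(E_prime_Pa = 6e3, E_dprime_Pa = 1.5e3, seed = 5)
  recs <- simulate_dynamic_response(sc, c(0.1, 0.5, 1, 2, 5, 10, 15))
  est <- run_viscoelastic_pipeline(recs)
  expect_rel(est$E_prime_Pa, 6e3, 0.08)
  expect_rel(est$E_dprime_Pa, 1.5e3, 0.12)
  expect_false(est$purely_elastic)
  expect_equal(est$tau_s, est$E_prime_Pa / est$E_dprime_Pa * 0.0703,
               tolerance = 1e-9)

  # purely elastic sweep
  sc0 <- synthetic_scenario(E_prime_Pa = 6e3, E_dprime_Pa = 0, seed = 5)
  recs0 <- simulate_dynamic_response(sc0, c(0.1, 1, 5, 10))
  est0 <- run_viscoelastic_pipeline(recs0)
  expect_true(est0$purely_elastic)
  expect_equal(est0$E_dprime_Pa, 0)

  # permutation invariance of the sweep order
  est_rev <- run_viscoelastic_pipeline(rev(recs))
  expect_equal(est_rev$E_prime_Pa, est$E_prime_Pa)
  expect_equal(est_rev$E_dprime_Pa, est$E_dprime_Pa)

  # missing anchor
  expect_error(run_viscoelastic_pipeline(recs[-1]),
               class = "magsense_protocol_error")
})

test_that("field linearity: amplitude scales with By in the forward model", {
  sc <- synthetic_scenario(E_prime_Pa = 4e3, E_dprime_Pa = 1e3, seed = 2)
  r1 <- simulate_dynamic_response(sc, 0.1, By_mT = 10)[[1]]
  r2 <- simulate_dynamic_response(sc, 0.1, By_mT = 15)[[1]]
  a1 <- amplitude_of(r1$time_s, r1$eyy_mean, 0.1) / 10
  a2 <- amplitude_of(r2$time_s, r2$eyy_mean, 0.1) / 15
  expect_rel(a1, a2, 0.01)
})

test_that("sweep CSV and estimate JSON round trip", {
  sc <- synthetic_scenario(E_prime_Pa = 3.2e3, E_dprime_Pa = 0.8e3, seed = 3)
  recs <- simulate_dynamic_response(sc, c(0.1, 1, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(recs, path)
  back <- read_sweep_csv(path)
  expect_length(back, 3)
  f_back <- unname(sort(vapply(back, `[[`, 0, "frequency_hz")))
  expect_equal(f_back, c(0.1, 1, 5))
  est <- run_viscoelastic_pipeline(back)
  jp <- withr::local_tempfile(fileext = ".json")
  write_visco_json(est, jp)
  out <- jsonlite::read_json(jp)
  expect_equal(out$E_prime_Pa, est$E_prime_Pa, tolerance = 1e-9)
})
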