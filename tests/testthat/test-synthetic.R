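# Synthetic-data generators: determinism, protocol semantics, forward laws,
# particles, rendering, configuration round trips.

test_that("detachment simulation follows the protocol semantics", {
  fx <- flat_sim()
  sim <- fx$sim
  expect_true(sim$truth$detached)
  expect_equal(sim$truth$Fa_N, 0.5e-3)
  # threshold frame: pull-off demand equals the adhesion at B_detach
  ti <- sim$truth$threshold_index
  expect_equal(sim$truth$tension_N[ti], 0.5e-3, tolerance = 1e-6)
  # fields of the stepping phase descend in -y
  expect_lt(sim$field$B[ti, 2], 0)
  # frames and field waveform stay aligned
  expect_length(sim$shapes, length(sim$field$time_s))
  expect_true(all(diff(sim$field$time_s) > 0))
})

test_that("zero adhesion detaches at the first step of the peel phase", {
  sc <- synthetic_scenario(Fa_N = 0, seed = 1)
  sim <- simulate_detachment_sequence(sc)
  expect_true(sim$truth$detached)
  expect_lte(sim$truth$threshold_index, 2)
  expect_lt(sim$truth$B_detach_mT, sc$protocol$dB_mT)
})

test_that("a protocol capped below the threshold reports not detached", {
  sc <- synthetic_scenario(Fa_N = 0.5e-3, seed = 1,
                           protocol = detachment_protocol(B_max_mT = 2))
  sim <- simulate_detachment_sequence(sc)
  expect_false(sim$truth$detached)
  expect_true(is.na(sim$truth$B_detach_mT))
})

test_that("simulations are deterministic for a fixed seed", {
  sc <- synthetic_scenario(Fa_N = 0.3e-3, tracking_noise_px = 1, seed = 42)
  s1 <- simulate_detachment_sequence(sc)
  s2 <- simulate_detachment_sequence(sc)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  sc2 <- synthetic_scenario(Fa_N = 0.3e-3, tracking_noise_px = 1, seed = 43)
  s3 <- simulate_detachment_sequence(sc2)
  expect_false(identical(s1$shapes[[1]]$x, s3$shapes[[1]]$x))
})

test_that("dynamic response follows the calibrated forward law", {
  # zero field: zero strain
  sc <- synthetic_scenario(E_prime_Pa = 3.2e3, E_dprime_Pa = 0, seed = 1)
  r0 <- simulate_dynamic_response(sc, 0.1, By_mT = 0)[[1]]
  expect_equal(max(abs(r0$eyy)), 0)

  # E' = 3.2 kPa, By = 20 mT, 0.1 Hz, purely elastic: mean-strain
  # amplitude ~ 0.197 straight from the power law
  r1 <- simulate_dynamic_response(sc, 0.1, By_mT = 20)[[1]]
  amp <- amplitude_of(r1$time_s, r1$eyy_mean, 0.1)
  expect_rel(amp, 54.128 * 3200^(-1.067) * 20, 0.02)
  expect_rel(amp, 0.197, 0.05)

  # >= 4 cycles per record and spatial coverage of the whole body
  expect_gte(max(r1$time_s) * r1$frequency_hz, 4)
  expect_equal(range(r1$s), c(0, sc$robot$L))
})

test_that("particle seeding and advection are seeded and exact", {
  ps <- seed_particles(c(0, 5e-3, 0, 2e-3), 100, seed = 31)
  ps_again <- seed_particles(c(0, 5e-3, 0, 2e-3), 100, seed = 31)
  expect_identical(ps, ps_again)
  # density 100/mm^2 over 10 mm^2 -> about 1000 particles
  expect_gt(nrow(ps), 1000 - 4 * sqrt(1000))
  expect_lt(nrow(ps), 1000 + 4 * sqrt(1000))

  adv0 <- advect_particles(ps, function(x, y)
    list(ux = rep(0, length(x)), uy = rep(0, length(x))))
  expect_equal(adv0$x, ps$x0)

  adv <- advect_particles(ps, function(x, y)
    list(ux = rep(5e-6, length(x)), uy = rep(0, length(x))))
  expect_equal(adv$x - ps$x0, rep(5e-6, nrow(ps)))

  expect_error(seed_particles(c(0, 0, 0, 1e-3), 100),
               class = "magsense_domain_error")
})

test_that("rendering is deterministic and noise-free renders are exact", {
  rb <- default_robot()
  s <- seq(0, rb$L, length.out = 65)
  bar <- beam_shape(s, theta = rep(0, 65), origin = c(-rb$L / 2, 0.5e-3))

  clean_optics <- render_optics(psf_sigma_px = 0, gauss_sd = 0,
                                photons = Inf)
  fr <- render_image_stack(shapes = list(bar), robot = rb,
                           optics = clean_optics, seed = 1)[[1]]
  # binary-like silhouette: only the two nominal levels appear
  expect_setequal(unique(as.numeric(fr$data)), c(0.75, 0.75 - 0.35))

  f1 <- render_image_stack(shapes = list(bar), robot = rb, seed = 9)
  f2 <- render_image_stack(shapes = list(bar), robot = rb, seed = 9)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))

  # TIFF + sidecar written together
  path <- withr::local_tempfile(fileext = ".tif")
  render_image_stack(shapes = list(bar), robot = rb, seed = 9, path = path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".truth.json")))
  truth <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_equal(truth$seed, 9)
})

test_that("configuration files round trip", {
  rb <- robot_spec(E = 150e3)
  rp <- withr::local_tempfile(fileext = ".json")
  write_robot_json(rb, rp)
  rb2 <- read_robot_json(rp)
  expect_equal(rb2$E, 150e3)
  expect_equal(rb2$L, rb$L)
  expect_equal(rb2$magnetization$phi(1e-3), rb$magnetization$phi(1e-3))

  sc <- synthetic_scenario(Fa_N = 0.3e-3, curvature = 150, seed = 7)
  sp <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(sc, sp)
  sc2 <- read_scenario_json(sp)
  expect_equal(sc2$Fa_N, 0.3e-3)
  expect_equal(sc2$curvature, 150)
  expect_equal(sc2$seed, 7L)
  expect_equal(sc2$protocol$B_load_mT, sc$protocol$B_load_mT)

  wf <- detachment_protocol()
  wp <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, wp)
  wf2 <- read_waveform_csv(wp)
  expect_equal(wf2$B, wf$B, tolerance = 1e-12)

  cal <- visco_calibration()
  cp <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, cp)
  cal2 <- read_calibration_json(cp)
  expect_equal(cal2$k, 54.128)
  expect_equal(cal2$a, -1.067)
  expect_equal(cal2$k_tau, 0.0703)
})
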