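# Digital image correlation and displacement-field processing.

particle_frame <- function(particles, seed) {
  render_image_stack(particles = list(particles),
                     optics = render_optics(pixel_pitch_m = 10e-6,
                                            width_px = 140, height_px = 140,
                                            origin_m = c(0, 0),
                                            psf_sigma_px = 1,
                                            gauss_sd = 0.004),
                     modality = "fluorescence", seed = seed)[[1]]
}

test_that("DIC recovers rigid shifts and the null field", {
  ps <- seed_particles(c(0, 1.4e-3, 0, 1.4e-3), 300, seed = 7)
  f1 <- particle_frame(ps, seed = 8)
  ps2 <- ps; ps2$x <- ps$x + 3 * 10e-6
  f2 <- particle_frame(ps2, seed = 8)
  dd <- compute_displacement_field(f1, f2, step_px = 16, max_shift_px = 6)
  expect_gt(sum(dd$valid), 10)
  expect_lt(max(abs(dd$ux_px[dd$valid] - 3)), 0.1)
  expect_lt(max(abs(dd$uy_px[dd$valid])), 0.1)

  d0 <- compute_displacement_field(f1, f1, step_px = 16, max_shift_px = 6)
  expect_lt(max(abs(c(d0$ux_px[d0$valid], d0$uy_px[d0$valid]))), 0.05)
})

test_that("DIC resolves a linear shear warp within 5%", {
  ps <- seed_particles(c(0, 1.4e-3, 0, 1.4e-3), 400, seed = 17)
  f1 <- particle_frame(ps, seed = 18)
  grad <- 0.02
  ps2 <- advect_particles(ps, function(x, y)
    list(ux = rep(0, length(x)), uy = grad * x))
  f2 <- particle_frame(ps2, seed = 18)
  dd <- compute_displacement_field(f1, f2, step_px = 12, max_shift_px = 6)
  ok <- dd$valid
  fit <- stats::lm(dd$uy[ok] ~ dd$x[ok])
  expect_rel(unname(stats::coef(fit)[2]), grad, 0.05)
})

test_that("point displacements are literal position differences", {
  ps <- seed_particles(c(0, 1e-3, 0, 1e-3), 100, seed = 3)
  pd0 <- point_displacements(ps)
  expect_equal(pd0$ux, rep(0, nrow(ps)))
  expect_equal(pd0$uy, rep(0, nrow(ps)))

  ps5 <- ps; ps5$x <- ps$x0 + 5 * 10e-6
  pd5 <- point_displacements(ps5)
  expect_equal(pd5$ux, rep(5e-5, nrow(ps)))

  field <- function(x, y) list(ux = 1e-5 * sin(2 * pi * x / 1e-3),
                               uy = -2e-5 * y / 1e-3)
  adv <- advect_particles(ps, field)
  pd <- point_displacements(adv)
  u_true <- field(ps$x0, ps$y0)
  expect_lt(max(abs(pd$ux - u_true$ux)), 1e-12)
  expect_lt(max(abs(pd$uy - u_true$uy)), 1e-12)

  ps_na <- ps; ps_na$x[3] <- NA
  expect_false(point_displacements(ps_na)$valid[3])
})

test_that("DIC and particle tracking agree on advected renders", {
  ps <- seed_particles(c(0, 1.4e-3, 0, 1.4e-3), 350, seed = 27)
  f1 <- particle_frame(ps, seed = 28)
  disp <- function(x, y) list(ux = rep(2.2e-5, length(x)),
                              uy = rep(-1.4e-5, length(x)))
  ps2 <- advect_particles(ps, disp)
  f2 <- particle_frame(ps2, seed = 28)
  dd <- compute_displacement_field(f1, f2, step_px = 16, max_shift_px = 6)
  ok <- dd$valid
  rms <- sqrt(mean(((dd$ux[ok] - 2.2e-5)^2 + (dd$uy[ok] + 1.4e-5)^2) /
                     (10e-6)^2))
  expect_lt(rms, 0.2)
})

test_that("interpolation preserves constants and reproduces linear fields", {
  set.seed(3)
  xs <- runif(80, 0, 1e-3); ys <- runif(80, 0, 1e-3)
  fc <- interpolate_smooth_field(xs, ys, ux = rep(2e-6, 80),
                                 uy = rep(-1e-6, 80))
  expect_lt(max(abs(fc$ux - 2e-6)), 1e-18)
  expect_lt(max(abs(fc$uy + 1e-6)), 1e-18)

  fl <- interpolate_smooth_field(xs, ys, ux = 0.01 * xs, uy = 0.02 * ys)
  gx <- matrix(fl$x, length(fl$y), length(fl$x), byrow = TRUE)
  gy <- matrix(fl$y, length(fl$y), length(fl$x))
  interior <- gx > 2e-4 & gx < 8e-4 & gy > 2e-4 & gy < 8e-4
  expect_lt(max(abs(fl$ux - 0.01 * gx)[interior]) / (0.01 * 1e-3), 0.01)

  expect_error(interpolate_smooth_field(1e-4, 1e-4, ux = 1e-6, uy = 0),
               class = "magsense_empty_field")
  expect_error(interpolate_smooth_field(c(1, 2, 3) * 1e-4,
                                        c(1, 2, 3) * 1e-4,
                                        ux = rep(0, 3), uy = rep(0, 3)),
               class = "magsense_empty_field")
})

test_that("maximum-displacement map implements the range magnitude", {
  mk <- function(ux, uy) structure(
    list(x = 1:4, y = 1:3, ux = matrix(ux, 3, 4), uy = matrix(uy, 3, 4)),
    class = "displacement_field")
  static <- list(mk(1e-6, 2e-6), mk(1e-6, 2e-6), mk(1e-6, 2e-6))
  expect_equal(max(max_displacement_map(static)), 0)

  # sinusoidal histories: du = sqrt((2A)^2 + (2B)^2)
  A <- 3e-6; B <- 1.5e-6
  tt <- seq(0, 2 * pi, length.out = 40)
  series <- lapply(tt, function(t) mk(A * sin(t), B * sin(t)))
  du <- max_displacement_map(series)
  expect_equal(max(du), sqrt(4 * A^2 + 4 * B^2), tolerance = 1e-3)
  uy_only <- lapply(tt, function(t) mk(0, A * sin(t)))
  expect_equal(max(max_displacement_map(uy_only)), 2 * A, tolerance = 1e-3)

  # invariance under permutation and time reversal
  perm <- series[c(17, 3, 40, 21, seq_along(tt)[-c(17, 3, 40, 21)])]
  expect_equal(max_displacement_map(perm), du)
  expect_equal(max_displacement_map(rev(series)), du)

  expect_error(max_displacement_map(series[1]),
               class = "magsense_domain_error")
})

test_that("interface strain differentiates the field beneath the curve", {
  gxv <- seq(0, 2e-3, length.out = 41)
  gyv <- seq(-1e-3, 1e-3, length.out = 41)
  mkf <- function(fun) structure(
    list(x = gxv, y = gyv, ux = outer(gyv, gxv, function(y, x) 0 * y),
         uy = outer(gyv, gxv, fun)), class = "displacement_field")
  cx <- seq(0.3e-3, 1.7e-3, length.out = 20)
  cy <- rep(0.5e-3, 20)

  comp <- mkf(function(y, x) -0.05 * y)
  expect_equal(strain_at_interface(cx, cy, comp), rep(-0.05, 20),
               tolerance = 1e-9)

  rigid <- mkf(function(y, x) 3e-6 + 0 * y)
  expect_lt(max(abs(strain_at_interface(cx, cy, rigid))), 1e-3)

  # misalignment correction scales the strain by 1/cos(phi)
  p <- misalignment_params(0.2e-3, 0.15e-3, 2e-3)
  e_corr <- strain_at_interface(cx, cy, comp, misalignment = p)
  expect_equal(e_corr, rep(-0.05, 20) / cos(p$phi_rad), tolerance = 1e-9)

  expect_error(strain_at_interface(cx, rep(-0.95e-3, 20), comp),
               class = "magsense_coverage_error")
})

test_that("field CSV export is re-readable", {
  f <- structure(list(x = c(1e-4, 2e-4), y = c(0, 1e-4),
                      ux = matrix(1e-6, 2, 2), uy = matrix(-2e-6, 2, 2)),
                 class = "displacement_field")
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(list(f, f), c(0, 0.5), path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 8)
  expect_equal(unique(back$ux_um), 1)
})
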