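# Shape tracking, misalignment correction, SNR, TIFF I/O.

render_one <- function(shape, seed = 2, ...) {
  render_image_stack(shapes = list(shape), robot = default_robot(),
                     optics = render_optics(...), seed = seed)[[1]]
}

test_that("straight bar is tracked straight to sub-pixel accuracy", {
  rb <- default_robot()
  s <- seq(0, rb$L, length.out = 65)
  bar <- beam_shape(s, theta = rep(0, 65), origin = c(-rb$L / 2, 0.5e-3))
  fr <- render_one(bar)
  cv <- extract_robot_curve(fr)
  expect_rel(attr(cv, "arc_length_m"), rb$L, 0.02)
  rms_px <- sqrt(mean((cv$y - mean(cv$y))^2)) / fr$pixel_pitch_m
  expect_lt(rms_px, 0.5)
})

test_that("circular arc curvature is recovered within 2%", {
  rb <- default_robot()
  s <- seq(0, rb$L, length.out = 65)
  R <- 5e-3
  arc <- beam_shape(s, theta = s / R, origin = c(-2.5e-3, 0.2e-3))
  fr <- render_one(arc, height_px = 500)
  cv <- extract_robot_curve(fr)
  # algebraic circle fit of the tracked points
  fit <- qr.coef(qr(cbind(2 * cv$x, 2 * cv$y, 1)), cv$x^2 + cv$y^2)
  R_fit <- sqrt(fit[3] + fit[1]^2 + fit[2]^2)
  expect_rel(1 / R_fit, 200, 0.02)
})

test_that("blank frames raise a no-robot error", {
  blank <- image_frame(matrix(0.75, 120, 200) +
                         matrix(rnorm(24000, 0, 0.005), 120), 10e-6)
  expect_error(extract_robot_curve(blank), class = "magsense_no_robot_error")
})

test_that("curve extraction is equivariant to translation and rotation", {
  rb <- default_robot()
  s <- seq(0, rb$L, length.out = 65)
  sh <- beam_shape(s, theta = 0.3 * sin(2 * pi * s / rb$L),
                   origin = c(-rb$L / 2, 0.8e-3))
  opt <- list(width_px = 760, height_px = 760, origin_m = c(-3.8e-3, -3.8e-3))
  fr <- render_one(sh, width_px = opt$width_px, height_px = opt$height_px,
                   origin_m = opt$origin_m)
  cv0 <- extract_robot_curve(fr)

  # translation by a whole pixel count
  shift_px <- 13
  sh_t <- beam_shape(s, theta = 0.3 * sin(2 * pi * s / rb$L),
                     origin = c(-rb$L / 2 + shift_px * 10e-6, 0.8e-3))
  cv_t <- extract_robot_curve(render_one(sh_t, width_px = opt$width_px,
                                         height_px = opt$height_px,
                                         origin_m = opt$origin_m))
  # curve-to-curve distance (parameterization-free): shifted-back curve
  # must lie on the original within half a pixel
  sfine <- seq(0, max(cv0$s), length.out = 1000)
  x0f <- stats::approx(cv0$s, cv0$x, sfine)$y
  y0f <- stats::approx(cv0$s, cv0$y, sfine)$y
  dists <- vapply(seq_len(nrow(cv_t)), function(i)
    min(sqrt((x0f - (cv_t$x[i] - shift_px * 10e-6))^2 +
               (y0f - cv_t$y[i])^2)), 0)
  # end samples carry the half-pixel ambiguity of the tip rasterization
  expect_lt(max(dists[3:63]) / 10e-6, 0.5)
  expect_lt(max(dists) / 10e-6, 1.5)

  # 90 degree rotation: rotate the pixel matrix counter-clockwise
  rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  fr90 <- image_frame(rot90(fr$data), fr$pixel_pitch_m, modality = fr$modality)
  cv90 <- extract_robot_curve(fr90)
  # in the physics frame the curve maps (x, y) -> (-y, x) up to the origin
  x_exp <- -cv0$y
  # allow reversed parameterization
  d1 <- max(abs(cv90$x - min(cv90$x) - (x_exp - min(x_exp))))
  cvr <- cv90[rev(seq_len(nrow(cv90))), ]
  d2 <- max(abs(cvr$x - min(cvr$x) - (x_exp - min(x_exp))))
  expect_lt(min(d1, d2) / fr$pixel_pitch_m, 0.5)
})

test_that("footpads are tracked with continuity checks", {
  rb <- default_robot()
  s <- seq(0, rb$L, length.out = 65)
  sh <- beam_shape(s, theta = rep(0, 65), origin = c(-rb$L / 2, 0.5e-3))
  frames <- lapply(1:3, function(i) render_one(sh, seed = i))
  tk <- track_footpads(frames)
  expect_equal(nrow(tk), 3)
  expect_lt(max(abs(tk$d - rb$L)), 2 * 10e-6)
  expect_lt(max(abs(diff(tk$d))), 10e-6)

  blank <- image_frame(matrix(0.75, nrow(frames[[1]]$data),
                              ncol(frames[[1]]$data)) +
                         matrix(rnorm(length(frames[[1]]$data), 0, 0.005),
                                nrow(frames[[1]]$data)), 10e-6)
  err <- tryCatch(track_footpads(list(frames[[1]], blank, frames[[2]])),
                  error = function(e) e)
  expect_s3_class(err, "magsense_tracking_loss")
  expect_match(conditionMessage(err), "frame 2")
})

test_that("tracked buckling sequence reproduces the footpad distance", {
  fx <- flat_sim()
  rb <- fx$scenario$robot
  idx <- c(2, fx$sim$truth$threshold_index)
  frames <- lapply(fx$sim$shapes[idx], function(sh)
    render_image_stack(shapes = list(sh), robot = rb,
                       optics = render_optics(), seed = 4)[[1]])
  tk <- track_footpads(frames, jump_limit_m = 2e-3)
  d_true <- vapply(fx$sim$shapes[idx], function(sh) attr(sh, "d"), 0)
  expect_lt(max(abs(tk$d - d_true) / d_true), 0.02)
  # arc length conserved across the bending sequence
  arcs <- vapply(attr(tk, "curves"), function(cv) attr(cv, "arc_length_m"), 0)
  expect_lt(max(abs(arcs - rb$L) / rb$L), 0.02)
})

test_that("misalignment correction implements the tilt factor", {
  p0 <- misalignment_params(0.15e-3, 0.15e-3, 2e-3)
  expect_equal(p0$phi_rad, 0)
  expect_equal(correct_misalignment(c(1, 2.5), p0), c(1, 2.5))

  p <- misalignment_params(0.20e-3, 0.15e-3, 2e-3)
  expect_equal(p$phi_rad, asin(0.025))
  expect_equal(correct_misalignment(1, p), 1 / cos(asin(0.025)))
  expect_rel(correct_misalignment(1, p), 1 / 0.99969, 1e-4)

  expect_error(misalignment_params(2.15e-3, 0.15e-3, 2e-3),
               class = "magsense_degenerate_geometry")

  # composition with the inverse transform is the identity
  uy <- seq(-5, 5, by = 0.5)
  expect_equal(correct_misalignment(uy, p) * cos(p$phi_rad), uy)
})

test_that("image SNR matches its construction", {
  set.seed(9)
  img <- matrix(rnorm(120 * 120, 0.2, 0.01), 120)
  bg_mask <- matrix(TRUE, 120, 120); bg_mask[40:80, 40:80] <- FALSE
  sig_mask <- !bg_mask
  s_bg <- sd(img[bg_mask]); m_bg <- mean(img[bg_mask])
  img[sig_mask] <- m_bg + 39 * s_bg
  fr <- image_frame(img, 10e-6)
  expect_equal(image_snr(fr, sig_mask, bg_mask), 39, tolerance = 1e-6)
  img2 <- img; img2[sig_mask] <- m_bg
  expect_equal(image_snr(image_frame(img2, 10e-6), sig_mask, bg_mask), 0)
  expect_error(image_snr(fr, sig_mask, sig_mask),
               class = "magsense_domain_error")
  flat <- image_frame(matrix(1, 10, 10), 1e-5)
  expect_error(image_snr(flat, flat$data > 2, flat$data > 0),
               class = "magsense_domain_error")
})

test_that("x-ray-like renders reach the documented contrast regime", {
  rb <- default_robot()
  s <- seq(0, rb$L, length.out = 65)
  bar <- beam_shape(s, theta = rep(0, 65), origin = c(-rb$L / 2, 0.5e-3))
  fr <- render_one(bar, seed = 6)
  sig <- fr$data < 0.55
  bg <- matrix(FALSE, nrow(fr$data), ncol(fr$data)); bg[1:40, ] <- TRUE
  expect_gte(image_snr(fr, sig, bg), 30)
})

test_that("TIFF stacks round trip at all supported depths", {
  set.seed(5)
  imgs <- list(matrix(runif(30 * 20), 20), matrix(runif(30 * 20), 20))
  for (bits in c(8, 16, 32)) {
    path <- withr::local_tempfile(fileext = ".tif")
    write_tiff(imgs, path, bits = bits)
    back <- read_tiff(path)
    expect_length(back, 2)
    tol <- switch(as.character(bits), "8" = 1 / 254, "16" = 1 / 65534,
                  "32" = 1e-6)
    expect_lt(max(abs(back[[1]] - imgs[[1]])), tol)
    expect_lt(max(abs(back[[2]] - imgs[[2]])), tol)
  }
})
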