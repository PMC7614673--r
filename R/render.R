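# Rasterization of synthetic scenes into image stacks (optical /
# x-ray-like / fluorescence), with Gaussian PSF blur and Poisson+Gaussian
# noise. Ground truth goes to a JSON sidecar next to the TIFF.

#' Imaging optics and noise settings for rendering
#'
#' The default x-ray-like contrast-to-noise ratio targets an SNR of about
#' 39 (robot vs background), mirroring the contrast regime of x-ray
#' tracking of the metal-loaded robot body.
#'
#' @param pixel_pitch_m pixel pitch (m/px).
#' @param width_px,height_px canvas size.
#' @param origin_m physical position of the bottom-left canvas corner
#'   (physics frame, m).
#' @param psf_sigma_px Gaussian point-spread sigma (px); 0 disables.
#' @param contrast robot/background intensity difference.
#' @param background background intensity.
#' @param gauss_sd Gaussian read-noise SD.
#' @param photons photon budget per unit intensity for Poisson shot noise;
#'   `Inf` disables.
#' @return list of class `render_optics`.
#' @export
render_optics <- function(pixel_pitch_m = 10e-6, width_px = 800,
                          height_px = 360, origin_m = c(-4e-3, -1.2e-3),
                          psf_sigma_px = 1, contrast = 0.35,
                          background = 0.75, gauss_sd = 0.008,
                          photons = 5e4) {
  stopifnot(pixel_pitch_m > 0)
  structure(list(pixel_pitch_m = pixel_pitch_m, width_px = width_px,
                 height_px = height_px, origin_m = origin_m,
                 psf_sigma_px = psf_sigma_px, contrast = contrast,
                 background = background, gauss_sd = gauss_sd,
                 photons = photons), class = "render_optics")
}

# physics (m) -> image indices; returns (row, col), row 1 = top
phys_to_img <- function(x, y, optics) {
  col <- (x - optics$origin_m[1]) / optics$pixel_pitch_m + 0.5
  row <- optics$height_px - (y - optics$origin_m[2]) / optics$pixel_pitch_m + 0.5
  cbind(row, col)
}

# paint a filled rectangle: pixels within half_t of `p` along `tangent`
# (behind the end point) and within half_w across it
paint_end_cap <- function(canvas, p_rc, tangent_rc, half_t_px, half_w_px,
                          value) {
  r0 <- round(p_rc[1]); c0 <- round(p_rc[2])
  r <- ceiling(half_t_px + half_w_px) + 1
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  along <- offs$dr * tangent_rc[1] + offs$dc * tangent_rc[2]
  across <- -offs$dr * tangent_rc[2] + offs$dc * tangent_rc[1]
  keep <- along >= -half_t_px & along <= 0.5 & abs(across) <= half_w_px
  rr <- r0 + offs$dr[keep]; cc <- c0 + offs$dc[keep]
  ok <- rr >= 1 & rr <= nrow(canvas) & cc >= 1 & cc <= ncol(canvas)
  canvas[cbind(rr[ok], cc[ok])] <- value
  canvas
}

# paint a disk of given value around (row, col) centres
paint_disks <- function(canvas, centres, radius_px, value) {
  r <- ceiling(radius_px)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2, ]
  for (i in seq_len(nrow(centres))) {
    rr <- round(centres[i, 1]) + offs$dr
    cc <- round(centres[i, 2]) + offs$dc
    ok <- rr >= 1 & rr <= nrow(canvas) & cc >= 1 & cc <= ncol(canvas)
    canvas[cbind(rr[ok], cc[ok])] <- value
  }
  canvas
}

#' Render a synthetic image stack
#'
#' Rasterizes robot shapes (side view, body thickness) and/or tracer
#' particles into a multi-page grayscale stack with Gaussian PSF blur and
#' seeded Poisson+Gaussian noise, optionally writing a TIFF plus a JSON
#' ground-truth sidecar.
#'
#' @param shapes list of [beam_shape()] (or `NULL`).
#' @param particles list of `particle_set`s, one per frame (or `NULL`).
#' @param robot a [robot_spec()] (for the body thickness).
#' @param optics a [render_optics()].
#' @param modality `"xray"`, `"optical"` or `"fluorescence"`.
#' @param seed RNG seed for the noise.
#' @param path optional TIFF output path; a `<path>.truth.json` sidecar is
#'   written alongside.
#' @return list of [image_frame()]s, invisibly when `path` is given.
#' @export
render_image_stack <- function(shapes = NULL, particles = NULL,
                               robot = robot_spec(),
                               optics = render_optics(),
                               modality = c("xray", "optical", "fluorescence"),
                               seed = 1L, path = NULL) {
  modality <- match.arg(modality)
  n_frames <- max(length(shapes), length(particles))
  if (n_frames == 0)
    stop_magsense("nothing to render", "magsense_domain_error")
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    canvas <- matrix(switch(modality, xray = optics$background,
                            optical = 0.1, fluorescence = 0.02),
                     optics$height_px, optics$width_px)
    if (!is.null(shapes) && i <= length(shapes)) {
      sh <- shapes[[i]]
      # dense resample along the curve so disks overlap; inset the ends by
      # the stroke radius so the flat-ended body keeps its true length
      inset <- robot$t / 2
      sd_ <- seq(min(sh$s) + inset, max(sh$s) - inset, length.out = 400)
      xc <- stats::approx(sh$s, sh$x, sd_)$y
      yc <- stats::approx(sh$s, sh$y, sd_)$y
      ctr <- phys_to_img(xc, yc, optics)
      level <- switch(modality, xray = optics$background - optics$contrast,
                      optical = 0.8, fluorescence = 0.02)
      half_px <- robot$t / 2 / optics$pixel_pitch_m
      canvas <- paint_disks(canvas, ctr, half_px, level)
      # flat end caps up to the true body ends
      m <- nrow(ctr)
      t1 <- ctr[1, ] - ctr[2, ]
      t2 <- ctr[m, ] - ctr[m - 1, ]
      e1 <- phys_to_img(stats::approx(sh$s, sh$x, min(sh$s))$y,
                        stats::approx(sh$s, sh$y, min(sh$s))$y, optics)[1, ]
      e2 <- phys_to_img(stats::approx(sh$s, sh$x, max(sh$s))$y,
                        stats::approx(sh$s, sh$y, max(sh$s))$y, optics)[1, ]
      canvas <- paint_end_cap(canvas, e1, t1 / sqrt(sum(t1^2)),
                              inset / optics$pixel_pitch_m + half_px,
                              half_px, level)
      canvas <- paint_end_cap(canvas, e2, t2 / sqrt(sum(t2^2)),
                              inset / optics$pixel_pitch_m + half_px,
                              half_px, level)
    }
    if (!is.null(particles) && i <= length(particles)) {
      pp <- particles[[i]]
      ctr <- phys_to_img(pp$x, pp$y, optics)
      spot <- switch(modality, fluorescence = 0.85, optical = 0.9,
                     xray = optics$background - optics$contrast / 2)
      canvas <- paint_disks(canvas, ctr, 1.5, spot)
    }
    if (optics$psf_sigma_px > 0)
      canvas <- blur_gaussian(canvas, optics$psf_sigma_px)
    if (is.finite(optics$photons))
      canvas <- matrix(stats::rpois(length(canvas),
                                    pmax(canvas, 0) * optics$photons) /
                         optics$photons,
                       nrow(canvas), ncol(canvas))
    if (optics$gauss_sd > 0)
      canvas <- canvas + matrix(stats::rnorm(length(canvas), 0,
                                             optics$gauss_sd),
                                nrow(canvas), ncol(canvas))
    image_frame(canvas, optics$pixel_pitch_m, time_s = i - 1,
                modality = modality)
  }))
  if (!is.null(path)) {
    write_tiff(lapply(frames, `[[`, "data"), path)
    truth <- list(seed = seed, modality = modality,
                  pixel_pitch_m = optics$pixel_pitch_m,
                  origin_m = optics$origin_m,
                  n_frames = n_frames)
    if (!is.null(shapes))
      truth$shapes <- lapply(shapes, function(sh)
        list(s = sh$s, x = sh$x, y = sh$y))
    if (!is.null(particles))
      truth$particles <- lapply(particles, function(p)
        list(x = p$x, y = p$y))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(frames))
  }
  frames
}
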