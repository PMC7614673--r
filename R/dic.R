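# Digital image correlation of tracer-particle images and displacement
# field processing: windowed normalized cross-correlation with sub-pixel
# refinement, scattered-sample interpolation and smoothing, the pointwise
# maximum-displacement map, and interface strain extraction.

#' Windowed digital image correlation
#'
#' For every grid point, correlates a square window of the reference frame
#' against the deformed frame over integer shifts up to `max_shift_px`,
#' using normalized cross-correlation, and refines the peak to sub-pixel
#' precision with a parabolic fit. Points whose correlation peak falls
#' below `min_score` are flagged invalid, never silently interpolated.
#'
#' @param reference,deformed [image_frame()]s of identical size.
#' @param window_px window side (px).
#' @param step_px grid spacing (px).
#' @param max_shift_px search radius (px).
#' @param min_score validity threshold on the correlation peak.
#' @return data frame `x_px, y_px` (window centres, image coordinates),
#'   `ux_px, uy_px` (displacement, image coordinates), `x, y, ux, uy`
#'   (physics frame, m), `score`, `valid`.
#' @export
compute_displacement_field <- function(reference, deformed, window_px = 32,
                                       step_px = 8, max_shift_px = 8,
                                       min_score = 0.6) {
  A <- reference$data; B <- deformed$data
  if (!all(dim(A) == dim(B)))
    stop_magsense("frames must have identical shape", "magsense_domain_error")
  if (window_px >= min(dim(A)))
    stop_magsense("window larger than image", "magsense_domain_error")
  hw <- window_px %/% 2
  margin <- hw + max_shift_px + 1
  rows <- seq(margin + 1, nrow(A) - margin, by = step_px)
  cols <- seq(margin + 1, ncol(A) - margin, by = step_px)
  shifts <- -max_shift_px:max_shift_px
  ns <- length(shifts)
  out <- vector("list", length(rows) * length(cols))
  k <- 0
  for (r in rows) for (cl in cols) {
    k <- k + 1
    W <- A[(r - hw):(r + hw - 1), (cl - hw):(cl + hw - 1)]
    Wc <- W - mean(W)
    sw <- sqrt(sum(Wc^2))
    cc <- matrix(-Inf, ns, ns)
    if (sw > 0) {
      for (i in seq_len(ns)) for (j in seq_len(ns)) {
        dr <- shifts[i]; dc <- shifts[j]
        P <- B[(r + dr - hw):(r + dr + hw - 1),
               (cl + dc - hw):(cl + dc + hw - 1)]
        Pc <- P - mean(P)
        sp <- sqrt(sum(Pc^2))
        cc[i, j] <- if (sp > 0) sum(Wc * Pc) / (sw * sp) else 0
      }
    }
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    score <- cc[pk[1], pk[2]]
    dy <- shifts[pk[1]]; dx <- shifts[pk[2]]
    # parabolic sub-pixel refinement of the peak position
    parab <- function(m1, m2, m3) {
      den <- m1 - 2 * m2 + m3
      if (!is.finite(den) || den >= 0) return(0)
      max(-0.5, min(0.5, (m1 - m3) / (2 * den)))
    }
    ddy <- if (pk[1] > 1 && pk[1] < ns)
      parab(cc[pk[1] - 1, pk[2]], cc[pk[1], pk[2]], cc[pk[1] + 1, pk[2]]) else 0
    ddx <- if (pk[2] > 1 && pk[2] < ns)
      parab(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]], cc[pk[1], pk[2] + 1]) else 0
    out[[k]] <- c(r, cl, dy + ddy, dx + ddx, score)
  }
  m <- do.call(rbind, out)
  pitch <- reference$pixel_pitch_m
  H <- nrow(A)
  df <- data.frame(
    x_px = m[, 2], y_px = m[, 1],
    ux_px = m[, 4], uy_px = m[, 3],
    x = (m[, 2] - 0.5) * pitch, y = (H - m[, 1] + 0.5) * pitch,
    ux = m[, 4] * pitch, uy = -m[, 3] * pitch,  # physics y is up
    score = m[, 5])
  df$valid <- df$score >= min_score
  df
}

#' Per-particle displacements
#'
#' Literal differences between current and reference particle positions.
#' Particles without a current position are flagged, not dropped.
#'
#' @param particles a `particle_set` (see [seed_particles()]).
#' @return data frame `id, x0, y0, ux, uy, valid`.
#' @export
point_displacements <- function(particles) {
  ux <- particles$x - particles$x0
  uy <- particles$y - particles$y0
  data.frame(id = particles$id, x0 = particles$x0, y0 = particles$y0,
             ux = ux, uy = uy, valid = is.finite(ux) & is.finite(uy))
}

#' Interpolate and smooth scattered displacement samples onto a grid
#'
#' Local linear (plane) fits over the nearest samples reproduce linear
#' fields exactly; a Gaussian kernel (sigma of one grid step by default)
#' then smooths the gridded field. Constant fields are preserved exactly.
#'
#' @param x,y sample positions (m).
#' @param ux,uy sample displacements (m).
#' @param valid logical mask of usable samples.
#' @param grid_x,grid_y grid node coordinates (m); default a 32-step grid
#'   over the sample bounding box.
#' @param smooth_sigma_steps Gaussian smoothing width in grid steps.
#' @param k_neighbors samples per local fit.
#' @return object of class `displacement_field`: list with `x`, `y`
#'   (vectors), `ux`, `uy` (matrices `length(y) x length(x)`).
#' @export
interpolate_smooth_field <- function(x, y, ux, uy, valid = NULL,
                                     grid_x = NULL, grid_y = NULL,
                                     smooth_sigma_steps = 1,
                                     k_neighbors = 8) {
  if (is.null(valid)) valid <- rep(TRUE, length(x))
  x <- x[valid]; y <- y[valid]; ux <- ux[valid]; uy <- uy[valid]
  if (length(x) < 3)
    stop_magsense("need >= 3 valid samples", "magsense_empty_field")
  if (abs(stats::cor(x, y)) > 1 - 1e-9 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_magsense("samples are collinear", "magsense_empty_field")
  if (is.null(grid_x)) grid_x <- seq(min(x), max(x), length.out = 33)
  if (is.null(grid_y)) grid_y <- seq(min(y), max(y), length.out = 33)
  k <- min(k_neighbors, length(x))
  fit_at <- function(gx, gy, v) {
    d2 <- (x - gx)^2 + (y - gy)^2
    idx <- order(d2)[seq_len(k)]
    X <- cbind(1, x[idx] - gx, y[idx] - gy)
    cf <- tryCatch(qr.coef(qr(X), v[idx]), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) mean(v[idx]) else cf[1]
  }
  UX <- outer(seq_along(grid_y), seq_along(grid_x),
              Vectorize(function(iy, ix) fit_at(grid_x[ix], grid_y[iy], ux)))
  UY <- outer(seq_along(grid_y), seq_along(grid_x),
              Vectorize(function(iy, ix) fit_at(grid_x[ix], grid_y[iy], uy)))
  if (smooth_sigma_steps > 0) {
    UX <- blur_gaussian(UX, smooth_sigma_steps)
    UY <- blur_gaussian(UY, smooth_sigma_steps)
  }
  structure(list(x = grid_x, y = grid_y, ux = UX, uy = UY),
            class = "displacement_field")
}

# separable Gaussian blur with edge renormalization (constants preserved)
blur_gaussian <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  ones <- matrix(1, nrow(m), ncol(m))
  conv1 <- function(mm) {
    out <- mm * kern[half + 1]
    for (d in seq_len(half)) {
      up <- rbind(mm[-seq_len(d), , drop = FALSE],
                  matrix(0, d, ncol(mm)))
      dn <- rbind(matrix(0, d, ncol(mm)),
                  mm[seq_len(nrow(mm) - d), , drop = FALSE])
      out <- out + kern[half + 1 + d] * up + kern[half + 1 - d] * dn
    }
    out
  }
  conv <- function(mm) t(conv1(t(conv1(mm))))
  conv(m) / conv(ones)
}

#' Maximum-displacement map over a time series
#'
#' Pointwise range magnitude over time:
#' `sqrt((max ux - min ux)^2 + (max uy - min uy)^2)`. Invariant to frame
#' order and time reversal.
#'
#' @param fields list of `displacement_field`s on a common grid (>= 2).
#' @return matrix `du` on the common grid, with the grid vectors as
#'   attributes `x`, `y`.
#' @export
max_displacement_map <- function(fields) {
  if (length(fields) < 2)
    stop_magsense("need >= 2 time points", "magsense_domain_error")
  ux_max <- ux_min <- fields[[1]]$ux
  uy_max <- uy_min <- fields[[1]]$uy
  for (f in fields[-1]) {
    ux_max <- pmax(ux_max, f$ux); ux_min <- pmin(ux_min, f$ux)
    uy_max <- pmax(uy_max, f$uy); uy_min <- pmin(uy_min, f$uy)
  }
  du <- sqrt((ux_max - ux_min)^2 + (uy_max - uy_min)^2)
  attr(du, "x") <- fields[[1]]$x
  attr(du, "y") <- fields[[1]]$y
  du
}

#' Interface normal strain along the robot curve
#'
#' Central-difference `d uy / d y` of the smoothed displacement field,
#' evaluated in a band just beneath the interface along the robot curve,
#' optionally corrected into the robot frame for plane misalignment.
#'
#' @param curve_x,curve_y robot curve positions (m), physics frame.
#' @param field a `displacement_field`.
#' @param band_m band depth beneath the interface (m).
#' @param misalignment optional [misalignment_params()] applied to `uy`
#'   before differencing.
#' @return vector `eyy` along the curve samples.
#' @export
strain_at_interface <- function(curve_x, curve_y, field, band_m = 0.2e-3,
                                misalignment = NULL) {
  uy <- field$uy
  if (!is.null(misalignment)) uy <- correct_misalignment(uy, misalignment)
  gx <- field$x; gy <- field$y
  dy <- band_m / 2
  ylo <- curve_y - band_m
  if (any(curve_x < min(gx) | curve_x > max(gx)) ||
      any(ylo - dy < min(gy)) || any(curve_y > max(gy) + band_m))
    stop_magsense("strain band extends outside the displacement field",
                  "magsense_coverage_error")
  bil <- function(xq, yq) {
    ix <- findInterval(xq, gx, all.inside = TRUE)
    iy <- findInterval(yq, gy, all.inside = TRUE)
    tx <- (xq - gx[ix]) / (gx[ix + 1] - gx[ix])
    ty <- (yq - gy[iy]) / (gy[iy + 1] - gy[iy])
    uy[cbind(iy, ix)] * (1 - tx) * (1 - ty) +
      uy[cbind(iy, ix + 1)] * tx * (1 - ty) +
      uy[cbind(iy + 1, ix)] * (1 - tx) * ty +
      uy[cbind(iy + 1, ix + 1)] * tx * ty
  }
  yc <- curve_y - band_m / 2   # band centre beneath the interface
  (bil(curve_x, yc + dy) - bil(curve_x, yc - dy)) / (2 * dy)
}

#' Write a displacement field series as long CSV
#'
#' Columns `t, x_mm, y_mm, ux_um, uy_um`.
#'
#' @param fields list of `displacement_field`s.
#' @param times time stamps (s), one per field.
#' @param path file path.
#' @export
write_field_csv <- function(fields, times, path) {
  rows <- do.call(rbind, lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    g <- expand.grid(y = seq_along(f$y), x = seq_along(f$x))
    data.frame(t = times[i], x_mm = f$x[g$x] * 1e3, y_mm = f$y[g$y] * 1e3,
               ux_um = f$ux[cbind(g$y, g$x)] * 1e6,
               uy_um = f$uy[cbind(g$y, g$x)] * 1e6)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
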