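# Robot shape tracking from image frames: segmentation, centerline
# extraction, spline fitting, footpad tracking, misalignment correction and
# image SNR.

#' Image frame container
#'
#' @param data numeric matrix of intensities (rows top-down, as read from a
#'   TIFF page).
#' @param pixel_pitch_m physical pixel pitch (m/px).
#' @param time_s acquisition time stamp (s).
#' @param modality `"optical"` (bright robot on dark), `"xray"` (dark robot
#'   on bright) or `"fluorescence"` (particle imaging).
#' @return object of class `image_frame`.
#' @export
image_frame <- function(data, pixel_pitch_m, time_s = 0,
                        modality = c("xray", "optical", "fluorescence")) {
  modality <- match.arg(modality)
  if (!is.matrix(data) || any(!is.finite(data)))
    stop_magsense("image data must be a finite numeric matrix",
                  "magsense_domain_error")
  if (!is_number(pixel_pitch_m) || pixel_pitch_m <= 0)
    stop_magsense("pixel pitch must be positive", "magsense_domain_error")
  structure(list(data = data, pixel_pitch_m = pixel_pitch_m,
                 time_s = time_s, modality = modality),
            class = "image_frame")
}

# Otsu's threshold on a numeric vector
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# binary dilation/erosion with a 3x3 structuring element
dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nrow(m), ncol(m))
    rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
    cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    out <- out | sh
  }
  out
}
erode3 <- function(m) !dilate3(!m)
close3 <- function(m) erode3(dilate3(m))

# connected-component labelling (8-connectivity) via row runs + union-find
largest_component <- function(mask) {
  nr <- nrow(mask)
  runs <- vector("list", nr)  # per row: matrix cols (start, end, label)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nlab <- 0L
  prev <- NULL
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) { runs[r] <- list(NULL); prev <- NULL; next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    cur <- cbind(start = starts[keep], end = ends[keep], label = 0L)
    for (k in seq_len(nrow(cur))) {
      lab <- 0L
      if (!is.null(prev)) {
        # 8-connectivity: overlap with one-pixel slack
        ov <- which(prev[, "start"] <= cur[k, "end"] + 1L &
                    prev[, "end"] >= cur[k, "start"] - 1L)
        for (j in ov) {
          pl <- find(prev[j, "label"])
          if (lab == 0L) lab <- pl
          else if (pl != lab) parent[pl] <- lab
        }
      }
      if (lab == 0L) {
        nlab <- nlab + 1L
        parent[nlab] <- nlab
        lab <- nlab
      }
      cur[k, "label"] <- lab
    }
    runs[[r]] <- cur
    prev <- cur
  }
  if (nlab == 0L) return(NULL)
  # resolve labels, take largest area
  areas <- numeric(nlab)
  for (r in seq_len(nr)) {
    cur <- runs[[r]]
    if (is.null(cur)) next
    for (k in seq_len(nrow(cur))) {
      l <- find(cur[k, "label"])
      areas[l] <- areas[l] + cur[k, "end"] - cur[k, "start"] + 1L
    }
  }
  best <- which.max(areas)
  out <- matrix(FALSE, nr, ncol(mask))
  for (r in seq_len(nr)) {
    cur <- runs[[r]]
    if (is.null(cur)) next
    for (k in seq_len(nrow(cur)))
      if (find(cur[k, "label"]) == best)
        out[r, cur[k, "start"]:cur[k, "end"]] <- TRUE
  }
  out
}

#' Extract the robot centerline curve from an image frame
#'
#' Pipeline: global threshold (Otsu) with modality-appropriate polarity,
#' morphological closing, largest connected component, orientation by
#' principal axis, per-bin transverse centroid, uniform arc-length
#' resampling and cubic smoothing-spline fit. Image coordinates (top-left
#' origin, y down) are converted to the physics frame (y up, metres) here.
#'
#' @param frame an [image_frame()].
#' @param n_samples arc-length samples of the returned curve.
#' @param min_area_px minimum foreground area; below it a no-robot error is
#'   raised.
#' @param spar smoothing parameter of the spline fit (`NULL` = GCV).
#' @return object of class `robot_curve`: data frame `s, x, y` (m) with
#'   attributes `footpads` (end points, m), `arc_length_m`, `pitch_m`.
#' @export
extract_robot_curve <- function(frame, n_samples = 65, min_area_px = 200,
                                spar = NULL) {
  img <- frame$data
  thr <- otsu_threshold(as.numeric(img))
  mask <- if (frame$modality == "xray") img < thr else img > thr
  # a featureless frame still splits under Otsu; demand real class
  # separation before accepting a segmentation
  m_fg <- mean(img[mask]); m_bg <- mean(img[!mask])
  s_w <- sqrt((stats::var(img[mask]) + stats::var(img[!mask])) / 2)
  if (!is.finite(s_w) || s_w == 0 || abs(m_fg - m_bg) / s_w < 4)
    stop_magsense("no robot-like contrast in the frame",
                  "magsense_no_robot_error")
  mask <- close3(mask)
  comp <- largest_component(mask)
  if (is.null(comp) || sum(comp) < min_area_px)
    stop_magsense("no robot-sized foreground component found",
                  "magsense_no_robot_error")
  idx <- which(comp, arr.ind = TRUE)
  # physics frame: x right, y up, metres
  px <- (idx[, 2] - 0.5) * frame$pixel_pitch_m
  py <- (nrow(img) - idx[, 1] + 0.5) * frame$pixel_pitch_m
  # principal axis
  cx <- mean(px); cy <- mean(py)
  cv <- stats::cov(cbind(px - cx, py - cy))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  ang <- atan2(ev[2], ev[1])
  u <- (px - cx) * cos(ang) + (py - cy) * sin(ang)
  v <- -(px - cx) * sin(ang) + (py - cy) * cos(ang)
  # transverse centroid per longitudinal bin (~1 px wide)
  nb <- max(16L, ceiling(diff(range(u)) / frame$pixel_pitch_m))
  bin <- cut(u, nb)
  ub <- tapply(u, bin, mean)
  vb <- tapply(v, bin, mean)
  ok <- is.finite(ub) & is.finite(vb)
  ub <- ub[ok]; vb <- vb[ok]
  o <- order(ub)
  ub <- ub[o]; vb <- vb[o]
  xb <- cx + ub * cos(ang) - vb * sin(ang)
  yb <- cy + ub * sin(ang) + vb * cos(ang)
  # arc-length resample + smoothing spline
  al <- c(0, cumsum(sqrt(diff(xb)^2 + diff(yb)^2)))
  ss <- seq(0, al[length(al)], length.out = n_samples)
  xs <- stats::approx(al, xb, ss)$y
  ys <- stats::approx(al, yb, ss)$y
  # refinement: the axis-binned centroids are biased where the body runs
  # steeply to the principal axis; re-centre each sample from the pixels
  # nearest to it, projected on the local normal
  for (pass in 1:2) {
    near <- vapply(seq_along(px), function(i)
      which.min((xs - px[i])^2 + (ys - py[i])^2), 0L)
    tx <- fd_deriv(ss, xs); ty <- fd_deriv(ss, ys)
    tn <- sqrt(tx^2 + ty^2)
    nxv <- -ty / tn; nyv <- tx / tn
    off <- vapply(seq_along(xs), function(k) {
      j <- near == k
      if (!any(j)) return(0)
      mean((px[j] - xs[k]) * nxv[k] + (py[j] - ys[k]) * nyv[k])
    }, 0)
    xs <- xs + off * nxv
    ys <- ys + off * nyv
    al <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
    ss <- seq(0, al[length(al)], length.out = n_samples)
    xs <- stats::approx(al, xs, ss)$y  # re-resample uniformly
    ys <- stats::approx(al, ys, ss)$y
  }
  # extend the ends along their tangents to the tips of the pixel support
  # (axis binning stops about half a body thickness short on steep ends)
  near <- vapply(seq_along(px), function(i)
    which.min((xs - px[i])^2 + (ys - py[i])^2), 0L)
  tx <- fd_deriv(ss, xs); ty <- fd_deriv(ss, ys)
  for (end in c(1L, n_samples)) {
    sgn <- if (end == 1L) -1 else 1
    tn <- sqrt(tx[end]^2 + ty[end]^2)
    ux <- sgn * tx[end] / tn; uyv <- sgn * ty[end] / tn
    j <- which(near == end | near == end + sgn * 1L)
    if (length(j)) {
      reach <- max((px[j] - xs[end]) * ux + (py[j] - ys[end]) * uyv)
      reach <- max(0, reach - 0.5 * frame$pixel_pitch_m)
      xs[end] <- xs[end] + reach * ux
      ys[end] <- ys[end] + reach * uyv
    }
  }
  al <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  ss <- seq(0, al[length(al)], length.out = n_samples)
  xs <- stats::approx(al, xs, ss)$y
  ys <- stats::approx(al, ys, ss)$y

  fx <- stats::smooth.spline(ss, xs, spar = spar)
  fy <- stats::smooth.spline(ss, ys, spar = spar)
  xs <- stats::predict(fx, ss)$y
  ys <- stats::predict(fy, ss)$y
  # re-parameterize by the arc length of the smoothed curve
  al2 <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  ss2 <- seq(0, al2[length(al2)], length.out = n_samples)
  xs <- stats::approx(al2, xs, ss2)$y
  ys <- stats::approx(al2, ys, ss2)$y
  structure(data.frame(s = ss2, x = xs, y = ys),
            class = c("robot_curve", "data.frame"),
            footpads = rbind(c(xs[1], ys[1]), c(xs[n_samples], ys[n_samples])),
            arc_length_m = al2[length(al2)],
            pitch_m = frame$pixel_pitch_m)
}

#' Convert a tracked curve to a beam shape
#'
#' @param curve a [robot_curve()] as returned by [extract_robot_curve()].
#' @param smooth,spar passed to [beam_shape()].
#' @return a [beam_shape()].
#' @export
as_beam_shape <- function(curve, smooth = TRUE, spar = NULL) {
  beam_shape(curve$s, x = curve$x, y = curve$y, smooth = smooth, spar = spar)
}

#' Track footpads across a frame sequence
#'
#' Extracts the robot curve on every frame, takes the curve ends as
#' footpads and checks inter-frame continuity of the footpad distance.
#'
#' @param frames list of [image_frame()].
#' @param jump_limit_m maximum allowed inter-frame change of the footpad
#'   distance (m).
#' @param ... passed to [extract_robot_curve()].
#' @return data frame with `frame, x1, y1, x2, y2, d` (m) and the curves as
#'   attribute `curves`.
#' @export
track_footpads <- function(frames, jump_limit_m = 0.5e-3, ...) {
  curves <- vector("list", length(frames))
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    cv <- tryCatch(extract_robot_curve(frames[[i]], ...), error = function(e) e)
    if (inherits(cv, "error"))
      stop_magsense(sprintf("tracking lost at frame %d: %s", i,
                            conditionMessage(cv)),
                    "magsense_tracking_loss")
    fp <- attr(cv, "footpads")
    # orient consistently (left footpad first)
    if (fp[1, 1] > fp[2, 1]) fp <- fp[2:1, ]
    d <- sqrt(sum((fp[2, ] - fp[1, ])^2))
    if (i > 1 && abs(d - rows[[i - 1]]$d) > jump_limit_m)
      stop_magsense(sprintf("footpad distance jump at frame %d (%.3g mm)",
                            i, abs(d - rows[[i - 1]]$d) * 1e3),
                    "magsense_tracking_loss")
    curves[[i]] <- cv
    rows[[i]] <- data.frame(frame = i, x1 = fp[1, 1], y1 = fp[1, 2],
                            x2 = fp[2, 1], y2 = fp[2, 2], d = d)
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}

#' Misalignment parameters
#'
#' The robot plane can be tilted about the imaging x axis; the tilt is
#' recoverable from the apparent (nominal) thickness `l` of the body:
#' `phi = arcsin((l - t)/w)` with real thickness `t` and width `w`.
#'
#' @param l_m nominal (apparent) thickness (m).
#' @param t_m real body thickness (m).
#' @param w_m real body width (m).
#' @param origin_m optional origin offset `c(x0, y0, z0)` of the robot
#'   frame in the imaging frame.
#' @return object of class `misalignment_params` with the angle `phi_rad`.
#' @export
misalignment_params <- function(l_m, t_m, w_m, origin_m = c(0, 0, 0)) {
  if (abs(l_m - t_m) >= w_m)
    stop_magsense("|l - t| must be smaller than w (tilt angle undefined)",
                  "magsense_degenerate_geometry")
  structure(list(l_m = l_m, t_m = t_m, w_m = w_m, origin_m = origin_m,
                 phi_rad = asin((l_m - t_m) / w_m)),
            class = "misalignment_params")
}

#' Correct detected displacements for plane misalignment
#'
#' The in-plane displacement detected in the imaging frame underestimates
#' the true one by the cosine of the tilt: `uy' = uy / cos(phi)`.
#'
#' @param uy detected displacement(s).
#' @param params a [misalignment_params()].
#' @return corrected displacement(s), same units as `uy`.
#' @export
correct_misalignment <- function(uy, params) {
  uy / cos(params$phi_rad)
}

#' Image signal-to-noise ratio
#'
#' `SNR = |mean(signal) - mean(background)| / sd(background)`. The
#' supplementary definition is not printed in the main text; this contrast
#' form is used and isolated here for replacement.
#'
#' @param frame an [image_frame()].
#' @param signal_mask,background_mask logical matrices selecting disjoint,
#'   non-empty pixel sets.
#' @return scalar SNR.
#' @export
image_snr <- function(frame, signal_mask, background_mask) {
  if (!any(signal_mask) || !any(background_mask))
    stop_magsense("masks must be non-empty", "magsense_domain_error")
  if (any(signal_mask & background_mask))
    stop_magsense("masks must be disjoint", "magsense_domain_error")
  sbg <- stats::sd(frame$data[background_mask])
  if (sbg == 0)
    stop_magsense("background has zero variance: SNR undefined",
                  "magsense_domain_error")
  abs(mean(frame$data[signal_mask]) - mean(frame$data[background_mask])) / sbg
}

#' Write / read robot curve series as CSV
#'
#' Long format `frame, s, x_mm, y_mm`.
#'
#' @param curves list of [robot_curve()] (or a single one).
#' @param path file path.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "robot_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(seq_along(curves), function(i)
    data.frame(frame = i, s = curves[[i]]$s, x_mm = curves[[i]]$x * 1e3,
               y_mm = curves[[i]]$y * 1e3)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
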