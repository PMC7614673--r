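#' Planar beam shape
#'
#' A sampled planar configuration of the robot body: material coordinates
#' `s`, slope angles `theta(s)` (rad, counter-clockwise from +x), curvatures
#' `dtheta_ds` (1/m) and positions `(x, y)` (m). The beam is inextensible, so
#' positions are the arc-length integral of `(cos(theta), sin(theta))`.
#'
#' Supply either `theta` (positions are integrated from `origin`) or `x`/`y`
#' (angles and curvatures are differentiated from positions, optionally
#' through a smoothing spline -- the path taken for noisy tracked shapes).
#'
#' @param s material coordinates (m), strictly increasing, uniform spacing.
#' @param theta slope angles (rad).
#' @param x,y positions (m).
#' @param origin position of the first sample when integrating from `theta`.
#' @param smooth logical; when deriving from positions, fit smoothing splines
#'   `x(s)`, `y(s)` before differentiating (recommended for tracked data).
#' @param spar smoothing parameter passed to [stats::smooth.spline()];
#'   `NULL` lets generalized cross-validation choose.
#' @param footpads material coordinates of the footpads (m); defaults to the
#'   end samples.
#' @return object of class `beam_shape`: a data frame with columns
#'   `s, theta, dtheta_ds, x, y` and attributes `footpads`, `d` (Euclidean
#'   footpad distance, m) and `consistency` (RMS position residual, m).
#' @export
beam_shape <- function(s, theta = NULL, x = NULL, y = NULL,
                       origin = c(0, 0), smooth = FALSE, spar = NULL,
                       footpads = NULL) {
  s <- as.numeric(s)
  if (length(s) < 5L || any(diff(s) <= 0))
    stop_magsense("s must be increasing with at least 5 samples",
                  "magsense_domain_error")
  if (is.null(theta)) {
    stopifnot(!is.null(x), !is.null(y))
    if (smooth) {
      fx <- stats::smooth.spline(s, x, spar = spar)
      fy <- stats::smooth.spline(s, y, spar = spar)
      x <- stats::predict(fx, s)$y
      y <- stats::predict(fy, s)$y
      dx <- stats::predict(fx, s, deriv = 1)$y
      dy <- stats::predict(fy, s, deriv = 1)$y
    } else {
      dx <- fd_deriv(s, x)
      dy <- fd_deriv(s, y)
    }
    theta <- unwrap_angle(atan2(dy, dx))
    dtheta_ds <- fd_deriv(s, theta)
  } else {
    theta <- as.numeric(theta)
    dtheta_ds <- fd_deriv(s, theta)
    x <- origin[1] + cumtrapz(s, cos(theta))
    y <- origin[2] + cumtrapz(s, sin(theta))
  }
  df <- data.frame(s = s, theta = theta, dtheta_ds = dtheta_ds, x = x, y = y)
  xi <- origin_free_integral(df)
  if (is.null(footpads)) footpads <- range(s)
  fp <- cbind(interp1(s, x, footpads, "footpad s"),
              interp1(s, y, footpads, "footpad s"))
  structure(df,
            class = c("beam_shape", "data.frame"),
            footpads = footpads,
            footpad_xy = fp,
            d = sqrt(sum((fp[2, ] - fp[1, ])^2)),
            consistency = xi)
}

# RMS residual between stored positions and re-integrated positions
origin_free_integral <- function(df) {
  xi <- df$x[1] + cumtrapz(df$s, cos(df$theta))
  yi <- df$y[1] + cumtrapz(df$s, sin(df$theta))
  sqrt(mean((xi - df$x)^2 + (yi - df$y)^2))
}

fd_deriv <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

unwrap_angle <- function(a) {
  da <- diff(a)
  corr <- cumsum(c(0, round(da / (2 * pi)))) * 2 * pi
  a - corr
}

#' @export
print.beam_shape <- function(x, ...) {
  cat(sprintf("<beam_shape> %d samples, s in [%.3g, %.3g] mm, d = %.3g mm\n",
              nrow(x), min(x$s) * 1e3, max(x$s) * 1e3, attr(x, "d") * 1e3))
  invisible(x)
}

#' Footpad distance ratio d/L
#' @param shape a [beam_shape()].
#' @param L reference length (m); default the sampled arc length.
#' @return scalar d/L.
#' @export
footpad_distance_ratio <- function(shape, L = diff(range(shape$s))) {
  attr(shape, "d") / L
}

#' Write / read a beam shape as CSV
#'
#' Columns `s, theta, dtheta_ds, x, y` (SI units). A shape series is stored
#' long with an extra leading `frame` column.
#'
#' @param shape a `beam_shape`, or a list of them for a series.
#' @param path file path.
#' @export
write_shape_csv <- function(shape, path) {
  if (inherits(shape, "beam_shape")) shape <- list(shape)
  rows <- do.call(rbind, lapply(seq_along(shape), function(i)
    cbind(frame = i, as.data.frame(shape[[i]]))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shape_csv
#' @param smooth,spar passed to [beam_shape()] when rebuilding each frame.
#' @return `read_shape_csv`: a list of `beam_shape` objects.
#' @export
read_shape_csv <- function(path, smooth = FALSE, spar = NULL) {
  df <- utils::read.csv(path)
  if (!"frame" %in% names(df)) df$frame <- 1
  lapply(split(df, df$frame), function(d) {
    sh <- beam_shape(d$s, x = d$x, y = d$y, smooth = smooth, spar = spar)
    if (!smooth && all(c("theta", "dtheta_ds") %in% names(d))) {
      # keep the stored angles: they are consistent with the positions and
      # avoid re-differentiation error
      sh$theta <- d$theta
      sh$dtheta_ds <- d$dtheta_ds
    }
    sh
  })
}
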