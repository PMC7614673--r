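# Small numeric helpers shared across modules.

#' Trapezoidal integration
#'
#' @param x ordinate vector (strictly increasing).
#' @param y values at `x`.
#' @return scalar integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# cumulative trapezoid, same length as x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# higher-order cumulative integral on a uniform grid (3-point per-interval
# Newton-Cotes; falls back to trapezoid for < 3 samples)
cumint_uniform <- function(h, f) {
  n <- length(f)
  if (n < 3) return(c(0, cumsum(h * (f[-n] + f[-1]) / 2)))
  seg <- numeric(n - 1)
  seg[1] <- h / 12 * (5 * f[1] + 8 * f[2] - f[3])
  i <- 3:n
  seg[i - 1] <- h / 12 * (-f[i - 2] + 8 * f[i - 1] + 5 * f[i])
  c(0, cumsum(seg))
}

# reverse cumulative sum: out[i] = sum(v[i:n])
revcumsum <- function(v) rev(cumsum(rev(v)))

# midpoint values of a node vector: cubic (4th-order) in the interior,
# linear at the boundary intervals
mid4 <- function(v) {
  n1 <- length(v)
  mid <- (v[-1] + v[-n1]) / 2
  if (n1 >= 4) {
    j <- 2:(n1 - 2)
    mid[j] <- (9 * (v[j] + v[j + 1]) - (v[j - 1] + v[j + 2])) / 16
  }
  mid
}

# midpoint first derivative: 4th-order in the interior, 2nd at the ends
dmid4 <- function(v, h) {
  n1 <- length(v)
  d <- diff(v) / h
  if (n1 >= 4) {
    j <- 2:(n1 - 2)
    d[j] <- (27 * (v[j + 1] - v[j]) - (v[j + 2] - v[j - 1])) / (24 * h)
  }
  d
}

#' Standard gravity (m/s^2)
#' @keywords internal
G_ACCEL <- 9.80665

stop_magsense <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "magsense_error")))
}

warn_magsense <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "magsense_warning")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# linear interpolation that errors (instead of NA) outside the support
interp1 <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) - 1e-12 | xout > max(x) + 1e-12))
    stop_magsense(sprintf("%s queried outside [%g, %g]", what, min(x), max(x)),
                  "magsense_domain_error")
  stats::approx(x, y, xout, rule = 2)$y
}
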