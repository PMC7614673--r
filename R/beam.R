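# Quasi-static planar elastica of the magnetized robot body.
#
# Formulation: for a segment running from a "start" end (clamped or pinned at
# a known position) to a "tip" end, static equilibrium of the far part of the
# beam about each node gives
#
#   EI dtheta/dxi (xi) = Mom(xi)
#   Mom(xi) = integral over [xi, l] of [ (r' - r(xi)) x f + tau ] + tip-force
#             moment,
#
# where xi is arc length measured from the start end, f is the distributed
# load (gravity), tau the distributed magnetic torque, and the tip force the
# boundary reaction. This holds for segments oriented either way along the
# material coordinate (dir = +1/-1); positions follow dr/dxi =
# dir * (cos(theta), sin(theta)). The discretized residuals (midpoint
# finite differences against trapezoid moment integrals) are solved by a
# damped Newton iteration with a finite-difference Jacobian, with parameter
# continuation in the applied field.

#' Distributed magnetic torque density
#'
#' Torque per unit length exerted on the body by a uniform field:
#' \eqn{\tau(s) = A\, [\mathbf{M}(s) \times \mathbf{B}]_z} with the local
#' magnetization rotated into the lab frame by the body slope
#' \eqn{\theta(s)}.
#'
#' @param profile a [magnetization_profile()].
#' @param area cross-section area (m^2).
#' @param field_T field vector `c(Bx, By)` in Tesla.
#' @param s material coordinates (m) at which to evaluate.
#' @param theta body slope angles at `s` (rad); 0 for the undeformed body.
#' @return torque density (N m / m) at each `s`.
#' @export
magnetic_torque_density <- function(profile, area, field_T, s, theta = 0) {
  if (any(!is.finite(field_T))) stop_magsense("field must be finite",
                                              "magsense_domain_error")
  ang <- theta + profile$phi(s)
  area * profile$M(s) * (cos(ang) * field_T[2] - sin(ang) * field_T[1])
}

# torque density for a robot_spec at deformed angles
robot_torque <- function(robot, s, theta, field_T) {
  magnetic_torque_density(robot$magnetization, robot$A, field_T, s, theta)
}

# reverse partial integral: out[i] = integral_{xi_i}^{xi_n} v dxi
rev_cumtrapz <- function(v, dxi) {
  I <- cumint_uniform(dxi, v)
  I[length(I)] - I
}

# Moment of all loads on the far segment [i..n] about each node i, given
# angles/positions and tip force (lab-frame vector, may be NULL).
far_moment <- function(xpos, ypos, fy, fx, tau, dxi, F_tip) {
  Pafy <- rev_cumtrapz(fy, dxi)
  Pafx <- rev_cumtrapz(fx, dxi)
  Pxfy <- rev_cumtrapz(xpos * fy, dxi)
  Pyfx <- rev_cumtrapz(ypos * fx, dxi)
  Ptau <- rev_cumtrapz(tau, dxi)
  mom <- Pxfy - xpos * Pafy - Pyfx + ypos * Pafx + Ptau
  if (!is.null(F_tip)) {
    n <- length(xpos)
    mom <- mom + (xpos[n] - xpos) * F_tip[2] - (ypos[n] - ypos) * F_tip[1]
  }
  mom
}

# Core segment solver.
#
# seg: list with
#   s_start, s_tip : material coordinates of the two ends (any order)
#   r0             : position of the start end
#   start          : "clamped" (theta0 given) | "pinned"
#   theta0         : clamp angle (rad) when start == "clamped"
#   tip            : "free" | "point" | "surface"
#   tip_target     : position (2-vec) for tip == "point"
#   sub            : substrate for tip == "surface"
#   n              : number of intervals
# Unknowns: free thetas (+ tip force components / normal magnitude).
# guess: optional list(theta, F) for warm starts.
elastica_segment <- function(robot, field_T, seg, guess = NULL,
                             gravity = G_ACCEL, tol = 1e-6, max_iter = 40) {
  n <- seg$n
  dirn <- sign(seg$s_tip - seg$s_start)
  svec <- seq(seg$s_start, seg$s_tip, length.out = n + 1)
  dxi <- abs(svec[2] - svec[1])
  EI <- robot$EI
  wline <- -robot$rho * robot$A * gravity  # gravity load density, y (N/m)
  Mscale <- EI / robot$L
  Fscale <- EI / robot$L^2

  clamped <- identical(seg$start, "clamped")
  nF <- switch(seg$tip, free = 0L, point = 2L, surface = 1L)
  n_th <- if (clamped) n else n + 1L

  unpack <- function(z) {
    th <- numeric(n + 1)
    if (clamped) {
      th[1] <- seg$theta0
      th[-1] <- z[seq_len(n)]
    } else th <- z[seq_len(n + 1)]
    Fz <- if (nF > 0) z[n_th + seq_len(nF)] * Fscale else NULL
    list(theta = th, F = Fz)
  }

  residual <- function(z) {
    u <- unpack(z)
    th <- u$theta
    xi <- abs(svec - seg$s_start)
    xpos <- seg$r0[1] + dirn * cumint_uniform(dxi, cos(th))
    ypos <- seg$r0[2] + dirn * cumint_uniform(dxi, sin(th))
    tau <- robot_torque(robot, svec, th, field_T)
    F_tip <- switch(seg$tip,
      free = NULL,
      point = u$F,
      surface = {
        nrm <- tip_normal(seg$sub, xpos[n + 1], ypos[n + 1])
        u$F * nrm
      })
    mom <- far_moment(xpos, ypos, rep(wline, n + 1), rep(0, n + 1), tau,
                      dxi, F_tip)
    r_ode <- (EI * dmid4(th, dxi) - mid4(mom)) / Mscale
    r_bc <- numeric(0)
    if (!clamped) r_bc <- mom[1] / Mscale
    r_tip <- switch(seg$tip,
      free = numeric(0),
      point = (c(xpos[n + 1], ypos[n + 1]) - seg$tip_target) / robot$L,
      surface = seg$sub$sdist(cbind(xpos[n + 1], ypos[n + 1])) / robot$L)
    c(r_ode, r_bc, r_tip)
  }

  z <- if (!is.null(guess)) {
    th_g <- guess$theta
    zz <- if (clamped) th_g[-1] else th_g
    c(zz, if (nF > 0) (guess$F %||% numeric(nF)) / Fscale else NULL)
  } else {
    th_g <- rep(if (clamped) seg$theta0 else 0, n + 1)
    c(if (clamped) th_g[-1] else th_g, numeric(nF))
  }

  res <- newton_fd(residual, z, tol = tol, max_iter = max_iter)
  u <- unpack(res$z)
  xi <- abs(svec - seg$s_start)
  xpos <- seg$r0[1] + dirn * cumint_uniform(dxi, cos(u$theta))
  ypos <- seg$r0[2] + dirn * cumint_uniform(dxi, sin(u$theta))
  F_tip <- switch(seg$tip,
    free = c(0, 0),
    point = u$F,
    surface = u$F * tip_normal(seg$sub, xpos[n + 1], ypos[n + 1]))
  list(s = svec, theta = u$theta, x = xpos, y = ypos,
       F_tip = F_tip, Fz = u$F, converged = res$converged,
       resid = res$fnorm, z = res$z,
       guess = list(theta = u$theta, F = u$F))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# outward surface normal at the contact implied by a tip position
tip_normal <- function(sub, x, y) {
  if (abs(sub$curvature) < 1e-9) return(c(0, 1))
  R <- 1 / sub$curvature
  v <- c(x, y - R)
  v <- v / sqrt(sum(v^2))
  if (sub$curvature > 0) -v else v
}

# damped Newton with finite-difference Jacobian
newton_fd <- function(fn, z, tol = 1e-6, max_iter = 40, fd_step = 1e-7) {
  f <- fn(z)
  fnorm <- sqrt(mean(f^2))
  for (it in seq_len(max_iter)) {
    if (fnorm < tol) break
    m <- length(z)
    J <- matrix(0, length(f), m)
    for (j in seq_len(m)) {
      zj <- z
      h <- fd_step * max(1, abs(z[j]))
      zj[j] <- zj[j] + h
      J[, j] <- (fn(zj) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e)
      tryCatch(qr.solve(J, -f, tol = 1e-14), error = function(e2) NULL))
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    improved <- FALSE
    while (lam >= 1e-4) {
      z_new <- z + lam * step
      f_new <- fn(z_new)
      fn_new <- sqrt(mean(f_new^2))
      if (is.finite(fn_new) && fn_new < fnorm) { improved <- TRUE; break }
      lam <- lam / 2
    }
    if (!improved) break
    z <- z_new; f <- f_new; fnorm <- fn_new
  }
  list(z = z, fnorm = fnorm, converged = fnorm < tol)
}

# Continuation wrapper: solve seg over a field ramp 0 -> field_T (and
# optionally a geometric blend), bisecting steps on failure.
elastica_continue <- function(robot, field_T, seg, guess = NULL,
                              n_steps = 4, tol = 1e-6, max_depth = 14) {
  sol <- NULL
  lam_done <- 0
  lam_next <- 1 / n_steps
  depth <- 0
  while (lam_done < 1 - 1e-12) {
    trial <- elastica_segment(robot, field_T * lam_next, seg,
                              guess = guess, tol = tol)
    if (trial$converged) {
      sol <- trial
      guess <- trial$guess
      lam_step <- lam_next - lam_done
      lam_done <- lam_next
      lam_next <- min(1, lam_done + lam_step * 2)
      depth <- 0
    } else {
      depth <- depth + 1
      if (depth > max_depth)
        stop_magsense(sprintf(
          "elastica continuation failed at %.1f%% of the field ramp (residual %.3g)",
          100 * lam_next, trial$resid), "magsense_solver_error")
      lam_next <- (lam_done + lam_next) / 2
    }
  }
  sol
}
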