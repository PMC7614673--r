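#' Magnetization profile of the robot body
#'
#' The robot body carries a programmed residual magnetization described by a
#' magnitude \eqn{M(s)} (A/m) and a phase angle \eqn{\phi(s)} (rad) along the
#' material coordinate \eqn{s \in [0, L]}. The phase is the angle of the local
#' magnetization vector measured in the undeformed body frame. The default is
#' a single-full-period harmonic phase, \eqn{\phi(s) = 2\pi s/L + \pi/2},
#' with a uniform magnitude; the quarter-turn offset makes +y/-y the patch
#' load/peel axis, matching the published field protocols.
#'
#' @param L body length (m).
#' @param M0 magnetization magnitude (A/m). The magnitude after pulse
#'   magnetization of the NdFeB-elastomer composite is not printed; the
#'   default 130 kA/m follows from the composite volume fraction implied by
#'   the 2.5 g/cm^3 density and reproduces the documented buckling
#'   reachability (footpad distance ratio down to 0.3 below 20 mT).
#' @param phase either a function of `s` returning radians, or `NULL` for the
#'   default single-period harmonic.
#' @param magnitude either a function of `s` returning A/m, or `NULL` for a
#'   uniform magnitude `M0`.
#' @param s,M,phi alternatively, sampled profiles (vectors over `s`); queries
#'   interpolate linearly.
#' @return an object of class `magnetization_profile` with query functions
#'   `$M(s)` and `$phi(s)`.
#' @export
magnetization_profile <- function(L, M0 = 130e3, phase = NULL, magnitude = NULL,
                                  s = NULL, M = NULL, phi = NULL) {
  stopifnot(is_number(L), L > 0)
  if (!is.null(s)) {
    stopifnot(length(s) == length(M), length(s) == length(phi))
    if (any(M < 0)) stop_magsense("magnetization magnitude must be >= 0",
                                  "magsense_domain_error")
    so <- order(s)
    s <- s[so]; M <- M[so]; phi <- phi[so]
    Mfun <- function(q) interp1(s, M, q, "magnetization coordinate s")
    pfun <- function(q) interp1(s, phi, q, "magnetization coordinate s")
  } else {
    Mfun0 <- if (is.null(magnitude)) function(q) rep(M0, length(q)) else magnitude
    pfun0 <- if (is.null(phase)) function(q) 2 * pi * q / L + pi / 2 else phase
    guard <- function(f) function(q) {
      if (any(q < -1e-12 | q > L + 1e-12))
        stop_magsense("material coordinate s outside [0, L]",
                      "magsense_domain_error")
      f(q)
    }
    Mfun <- guard(Mfun0); pfun <- guard(pfun0)
  }
  structure(list(L = L, M = Mfun, phi = pfun, M0 = M0), class = "magnetization_profile")
}

#' Robot specification
#'
#' Geometry, elastic constants and magnetization of the beam-like soft robot.
#' Defaults correspond to the finalized design: a 6.5 mm x 2 mm x 0.15 mm
#' body (thickness-to-length ratio 0.023) of NdFeB-elastomer composite with
#' Young's modulus 163 kPa and density 2.5 g/cm^3, footpads at the body ends
#' and a 0.5 mm adhesive patch bonded at the middle of the body.
#'
#' @param L body length (m).
#' @param w body width (m).
#' @param t body thickness (m).
#' @param E Young's modulus (Pa).
#' @param rho density (kg/m^3).
#' @param Kr bulk modulus (Pa); only carried through to the interface stress
#'   scaling, not used by the beam solver.
#' @param magnetization a [magnetization_profile()]; default harmonic profile.
#' @param footpads material coordinates of the two footpads (m).
#' @param patch_center,patch_length material centre and length of the
#'   adhesive patch (m).
#' @return object of class `robot_spec`.
#' @export
robot_spec <- function(L = 6.5e-3, w = 2e-3, t = 0.15e-3,
                       E = 163e3, rho = 2500, Kr = 1e9,
                       magnetization = NULL,
                       footpads = c(0, L),
                       patch_center = L / 2, patch_length = 0.5e-3) {
  stopifnot(is_number(L), L > 0, is_number(w), w > 0, is_number(t), t > 0,
            is_number(E), E > 0, is_number(rho), rho > 0)
  if (length(footpads) != 2L || any(footpads < 0 | footpads > L) ||
      footpads[1] == footpads[2])
    stop_magsense("footpads must be two distinct coordinates in [0, L]",
                  "magsense_domain_error")
  if (is.null(magnetization)) magnetization <- magnetization_profile(L)
  obj <- list(L = L, w = w, t = t, E = E, rho = rho, Kr = Kr,
              magnetization = magnetization,
              footpads = sort(footpads),
              patch_center = patch_center, patch_length = patch_length)
  obj$A <- w * t                 # cross-section area (m^2)
  obj$I <- w * t^3 / 12          # second moment of area (m^4)
  obj$EI <- E * obj$I            # bending stiffness (N m^2)
  obj$weight <- rho * obj$A * L * G_ACCEL  # total body weight (N)
  obj$TLR <- t / L
  class(obj) <- "robot_spec"
  obj
}

#' @export
print.robot_spec <- function(x, ...) {
  cat(sprintf("<robot_spec> L=%.3g mm w=%.3g mm t=%.3g mm (TLR %.3f)\n",
              x$L * 1e3, x$w * 1e3, x$t * 1e3, x$TLR))
  cat(sprintf("  E=%.3g kPa rho=%.3g g/cm^3 EI=%.3g N m^2 weight=%.3g mN\n",
              x$E / 1e3, x$rho / 1e3, x$EI, x$weight * 1e3))
  invisible(x)
}

#' Magnetic field waveform
#'
#' Time-stamped uniform magnetic field vectors. Fields are stored in Tesla;
#' constructors accept mT for convenience since protocols are specified in mT.
#'
#' @param time_s strictly increasing time stamps (s).
#' @param Bx_mT,By_mT field components (mT).
#' @param kind protocol kind, one of `"load-step-detach"`, `"rotating"`,
#'   `"custom"`.
#' @param frequency_hz rotation frequency (Hz) for rotating waveforms.
#' @return object of class `field_waveform` with elements `time_s`, `B`
#'   (n x 2 matrix, Tesla), `kind`, `frequency_hz`.
#' @export
field_waveform <- function(time_s, Bx_mT = 0, By_mT = 0, kind = "custom",
                           frequency_hz = NULL) {
  n <- length(time_s)
  if (n > 1 && any(diff(time_s) <= 0))
    stop_magsense("time stamps must be strictly increasing", "magsense_domain_error")
  B <- cbind(rep_len(Bx_mT, n), rep_len(By_mT, n)) * 1e-3
  if (kind == "rotating") {
    mag <- sqrt(rowSums(B^2))
    if (diff(range(mag)) > 1e-9 + 1e-6 * max(mag))
      stop_magsense("rotating waveform must have constant |B|", "magsense_domain_error")
  }
  structure(list(time_s = as.numeric(time_s), B = B, kind = kind,
                 frequency_hz = frequency_hz,
                 omega = if (is.null(frequency_hz)) NULL else 2 * pi * frequency_hz),
            class = "field_waveform")
}

#' Staircase detachment-protocol waveform
#'
#' Builds the load-step-detach waveform: a loading field along +y held for
#' `load_dwell_s`, then steps of increasing magnitude along -y held for
#' `step_dwell_s` each, up to `B_max_mT`. The default protocol (13.4 mT load
#' for 5 s, 2.7 mT steps every 2.5 s) is the one used for the adhesion
#' sensing demonstrations; an alternative 10 mT / 2 mT variant is also in
#' use and can be expressed with the same arguments.
#'
#' @param B_load_mT loading field magnitude (mT), applied along +y.
#' @param load_dwell_s dwell of the loading step (s).
#' @param dB_mT step increment (mT).
#' @param step_dwell_s dwell per step (s).
#' @param B_max_mT maximum field magnitude of the stepping phase (mT).
#' @return [field_waveform()] of kind `"load-step-detach"`.
#' @export
detachment_protocol <- function(B_load_mT = 13.4, load_dwell_s = 5,
                                dB_mT = 2.7, step_dwell_s = 2.5,
                                B_max_mT = 40) {
  stopifnot(B_load_mT > 0, dB_mT > 0, step_dwell_s > 0, load_dwell_s > 0)
  steps <- seq(0, B_max_mT, by = dB_mT)
  time_s <- c(0, load_dwell_s + steps / dB_mT * step_dwell_s)
  By <- c(B_load_mT, -steps)
  wf <- field_waveform(time_s, Bx_mT = 0, By_mT = By, kind = "load-step-detach")
  wf$B_load_mT <- B_load_mT
  wf$dB_mT <- dB_mT
  wf$step_dwell_s <- step_dwell_s
  wf$B_max_mT <- B_max_mT
  wf
}

#' Rotating-field waveform
#'
#' @param By_mT field magnitude (mT).
#' @param frequency_hz rotation frequency (Hz).
#' @param n_cycles number of full cycles.
#' @param samples_per_cycle time samples per cycle.
#' @return [field_waveform()] of kind `"rotating"`.
#' @export
rotating_waveform <- function(By_mT, frequency_hz, n_cycles = 4,
                              samples_per_cycle = 40) {
  tt <- seq(0, n_cycles / frequency_hz, length.out = n_cycles * samples_per_cycle + 1)
  ph <- 2 * pi * frequency_hz * tt
  field_waveform(tt, Bx_mT = By_mT * cos(ph), By_mT = By_mT * sin(ph),
                 kind = "rotating", frequency_hz = frequency_hz)
}

#' Substrate surface geometry
#'
#' Circular-arc substrate of signed curvature `curvature` (1/m); positive
#' curvature is a concave bowl (centre of curvature above the surface, on the
#' robot side), negative a convex bump, zero a flat surface. The surface is
#' parameterized by arc length `u` with `u = 0` at the origin, and the robot
#' side is the +y side.
#'
#' @param curvature signed curvature (1/m).
#' @return object of class `substrate` with functions `$point(u)` (2-col
#'   matrix), `$angle(u)` (tangent angle, rad), `$normal(u)` (outward normal,
#'   2-col matrix) and `$sdist(xy)` (signed distance of points to the
#'   surface, positive on the robot side).
#' @export
substrate <- function(curvature = 0) {
  c0 <- curvature
  if (abs(c0) < 1e-9) {
    point <- function(u) cbind(u, 0 * u)
    angle <- function(u) rep(0, length(u))
    normal <- function(u) cbind(0 * u, 1 + 0 * u)
    sdist <- function(xy) xy[, 2]
  } else {
    R <- 1 / c0  # signed radius; centre at (0, R)
    point <- function(u) cbind(R * sin(u / R), R * (1 - cos(u / R)))
    angle <- function(u) u / R
    normal <- function(u) cbind(-sin(u / R), cos(u / R))
    sdist <- function(xy) {
      # signed distance, positive toward robot side (+y at u = 0)
      d <- sqrt(xy[, 1]^2 + (xy[, 2] - R)^2)
      if (c0 > 0) R - d else d - (-R)
    }
  }
  structure(list(curvature = c0, point = point, angle = angle,
                 normal = normal, sdist = sdist), class = "substrate")
}
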