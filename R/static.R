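# User-facing static equilibrium solvers built on the elastica core.

# generic one-parameter continuation: fun(lambda, guess) must return a list
# with $converged and $guess; lambda is ramped 0 -> 1 with step bisection.
continuation <- function(fun, guess, n_steps = 4, max_depth = 14,
                         max_total = 200) {
  sol <- NULL
  lam_done <- 0
  lam_next <- 1 / n_steps
  depth <- 0
  total <- 0
  while (lam_done < 1 - 1e-12) {
    total <- total + 1
    if (total > max_total)
      stop_magsense(sprintf(
        "continuation exceeded %d solves at %.1f%% (likely a fold in the equilibrium path)",
        max_total, 100 * lam_done), "magsense_solver_error")
    trial <- tryCatch(fun(lam_next, guess), error = function(e) e)
    ok <- !inherits(trial, "error") && isTRUE(trial$converged)
    if (ok) {
      sol <- trial
      guess <- trial$guess
      step <- lam_next - lam_done
      lam_done <- lam_next
      lam_next <- min(1, lam_done + 2 * step)
      depth <- 0
    } else {
      depth <- depth + 1
      if (depth > max_depth)
        stop_magsense(sprintf("continuation failed at %.1f%%: %s",
                              100 * lam_next,
                              if (inherits(trial, "error"))
                                conditionMessage(trial) else
                                sprintf("residual %.3g", trial$resid)),
                      "magsense_solver_error")
      lam_next <- (lam_done + lam_next) / 2
    }
  }
  sol
}

# initial sine-lobe guess for a buckled half of material length ell whose
# chord must shrink to `chord`
lobe_guess <- function(ell, chord, n, sign = 1) {
  ratio <- min(chord / ell, 0.999)
  alpha <- uniroot(function(a) {
    xi <- seq(0, 1, length.out = 101)
    mean(cos(a * sin(pi * xi))) - ratio
  }, c(1e-4, 2.9))$root
  xi <- seq(0, 1, length.out = n + 1)
  list(theta = sign * alpha * sin(pi * xi), F = c(0, 0))
}

# Attached "pinned-fixed-pinned" equilibrium: adhesive patch conforming to
# the substrate (clamped), footpads pinned at surface arc coordinates -u_f
# and +u_f. Returns forces and the patch holding tension. Warm-startable via
# `state` (a previous return value).
solve_attached_state <- function(robot, sub, uf, field_T, state = NULL,
                                 n_half = 30, tol = 1e-6) {
  h <- robot$patch_length / 2
  if (!isTRUE(all.equal(robot$footpads, c(0, robot$L))))
    stop_magsense("attached solve requires footpads at the body ends",
                  "magsense_domain_error")
  ell_L <- robot$patch_center - h
  ell_R <- robot$L - robot$patch_center - h

  mk_segs <- function(sb) {
    eL <- sb$point(-h)[1, ]; eR <- sb$point(h)[1, ]
    list(
      L = list(s_start = robot$patch_center - h, s_tip = 0, r0 = eL,
               start = "clamped", theta0 = sb$angle(-h), tip = "point",
               tip_target = sb$point(-uf)[1, ], n = n_half),
      R = list(s_start = robot$patch_center + h, s_tip = robot$L, r0 = eR,
               start = "clamped", theta0 = sb$angle(h), tip = "point",
               tip_target = sb$point(uf)[1, ], n = n_half))
  }

  if (is.null(state)) {
    # cold start: flat lobe at B = 0, then ramp curvature, then field
    gL <- lobe_guess(ell_L, uf - h, n_half, sign = -1)
    gR <- lobe_guess(ell_R, uf - h, n_half, sign = +1)
    segs <- mk_segs(substrate(0))
    sL <- elastica_segment(robot, c(0, 0), segs$L, guess = gL, tol = tol)
    sR <- elastica_segment(robot, c(0, 0), segs$R, guess = gR, tol = tol)
    if (!sL$converged || !sR$converged)
      stop_magsense("attached cold start failed to converge",
                    "magsense_solver_error")
    if (abs(sub$curvature) > 1e-9) {
      ramp <- function(side) function(lam, guess) {
        sg <- mk_segs(substrate(lam * sub$curvature))[[side]]
        elastica_segment(robot, c(0, 0), sg, guess = guess, tol = tol)
      }
      sL <- continuation(ramp("L"), sL$guess)
      sR <- continuation(ramp("R"), sR$guess)
    }
    B_from <- c(0, 0)
    gL <- sL$guess; gR <- sR$guess
  } else {
    B_from <- state$field_T
    gL <- state$gL; gR <- state$gR
  }

  segs <- mk_segs(sub)
  step <- function(side, g) {
    fun <- function(lam, guess) {
      B <- B_from + lam * (field_T - B_from)
      elastica_segment(robot, B, segs[[side]], guess = guess, tol = tol)
    }
    # warm starts usually take the full step; bisection kicks in on failure
    continuation(fun, g, n_steps = if (is.null(state)) 4 else 1)
  }
  sL <- step("L", gL)
  sR <- step("R", gR)

  F1 <- sL$F_tip; F2 <- sR$F_tip
  F_adh <- c(0, robot$weight) - F1 - F2      # force the adhesive must supply
  n_p <- sub$normal(0)[1, ]
  tension <- -sum(F_adh * n_p)               # pull-off demand on the patch
  list(field_T = field_T, sub = sub, uf = uf, n_half = n_half,
       gL = sL$guess, gR = sR$guess, sL = sL, sR = sR,
       F1 = F1, F2 = F2, tension = tension)
}

# combined 0..L beam_shape from an attached state (patch conforms to surface)
attached_shape <- function(robot, st) {
  h <- robot$patch_length / 2
  n_patch <- max(3L, round(robot$patch_length / (robot$L / 65) / 1))
  up <- seq(-h, h, length.out = n_patch + 1)
  pp <- st$sub$point(up)
  sL <- st$sL; sR <- st$sR
  s <- c(rev(sL$s), robot$patch_center + up[-c(1, n_patch + 1)], sR$s)
  th <- c(rev(sL$theta), st$sub$angle(up)[-c(1, n_patch + 1)], sR$theta)
  x <- c(rev(sL$x), pp[-c(1, n_patch + 1), 1], sR$x)
  y <- c(rev(sL$y), pp[-c(1, n_patch + 1), 2], sR$y)
  shp <- beam_shape(s, x = x, y = y, footpads = robot$footpads)
  # positions are exact; recompute theta from solver values (no smoothing)
  shp$theta <- th
  shp$dtheta_ds <- fd_deriv(s, th)
  shp
}

# Detached equilibrium: footpads pinned at the surface positions, patch free.
solve_detached_state <- function(robot, sub, uf, field_T, guess = NULL,
                                 n = 60, tol = 1e-6) {
  seg <- list(s_start = 0, s_tip = robot$L, r0 = sub$point(-uf)[1, ],
              start = "pinned", tip = "point",
              tip_target = sub$point(uf)[1, ], n = n)
  if (is.null(guess)) {
    # arc-like initial guess bulging away from the substrate
    ratio <- chord_of(sub, uf) / robot$L
    g <- lobe_guess(robot$L, chord_of(sub, uf), n, sign = +1)
    guess <- list(theta = g$theta, F = c(0, 0))
  }
  fun <- function(lam, g) elastica_segment(robot, field_T * lam, seg,
                                           guess = g, tol = tol)
  sol <- continuation(fun, guess)
  shp <- beam_shape(sol$s, x = sol$x, y = sol$y, footpads = robot$footpads)
  shp$theta <- sol$theta
  shp$dtheta_ds <- fd_deriv(sol$s, sol$theta)
  list(shape = shp, sol = sol, guess = sol$guess)
}

# chord distance between surface points at arc coords -uf, +uf
chord_of <- function(sub, uf) {
  p <- sub$point(c(-uf, uf))
  sqrt(sum((p[2, ] - p[1, ])^2))
}

# surface arc coordinate giving footpad chord distance d
uf_for_chord <- function(sub, d) {
  if (abs(sub$curvature) < 1e-9) return(d / 2)
  R <- abs(1 / sub$curvature)
  if (d / 2 > R) stop_magsense("footpad chord exceeds substrate diameter",
                               "magsense_domain_error")
  R * asin(d / (2 * R))
}

#' Solve the static robot shape under a uniform field
#'
#' Quasi-static nonlinear elastica equilibrium of the magnetized body:
#' bending stiffness balances the distributed magnetic torque, gravity and
#' the boundary reactions.
#'
#' Boundary kinds:
#' \describe{
#'   \item{`free-free`}{floating beam, gravity ignored (a free body has no
#'     static equilibrium under gravity); position gauge at the origin.}
#'   \item{`pinned-pinned`}{both footpads resting on the substrate; the
#'     first is held at the surface origin, the second slides on the surface
#'     (normal reaction). Used for buckling-reachability sweeps: the footpad
#'     distance `d` is an output.}
#'   \item{`pinned-fixed-pinned`}{adhesive patch conforming to (fixed on)
#'     the substrate, footpads pinned at surface positions with chord
#'     distance `d`. The attached sensing configuration.}
#' }
#'
#' @param robot a [robot_spec()].
#' @param field_mT field vector `c(Bx, By)` in mT; `|B|` must not exceed
#'   `B_limit_mT`.
#' @param boundary one of `"free-free"`, `"pinned-pinned"`,
#'   `"pinned-fixed-pinned"`.
#' @param sub a [substrate()] (flat default).
#' @param d footpad chord distance (m) for the attached boundary; default
#'   `0.8 * L`.
#' @param n number of intervals for the discretization (65 nodes default).
#' @param B_limit_mT configured maximum field magnitude.
#' @return a [beam_shape()]; for the attached boundary, with attributes
#'   `F1`, `F2` (footpad reaction vectors, N) and `patch_tension` (N, the
#'   pull-off demand on the adhesive).
#' @export
solve_static_shape <- function(robot, field_mT = c(0, 0),
                               boundary = c("pinned-pinned",
                                            "pinned-fixed-pinned",
                                            "free-free"),
                               sub = substrate(0), d = 0.75 * robot$L,
                               n = 64, B_limit_mT = 60) {
  boundary <- match.arg(boundary)
  if (sqrt(sum(field_mT^2)) > B_limit_mT)
    stop_magsense(sprintf("|B| exceeds configured maximum %g mT", B_limit_mT),
                  "magsense_domain_error")
  field_T <- field_mT * 1e-3
  if (boundary == "free-free") {
    seg <- list(s_start = 0, s_tip = robot$L, r0 = c(0, 0),
                start = "pinned", tip = "free", n = n)
    fun <- function(lam, g) elastica_segment(robot, field_T * lam, seg,
                                             guess = g, gravity = 0)
    sol <- continuation(fun, list(theta = rep(0, n + 1)))
    shp <- beam_shape(sol$s, x = sol$x, y = sol$y, footpads = robot$footpads)
    shp$theta <- sol$theta
    shp$dtheta_ds <- fd_deriv(sol$s, sol$theta)
    return(shp)
  }
  if (boundary == "pinned-pinned") {
    seg <- list(s_start = 0, s_tip = robot$L, r0 = sub$point(0)[1, ],
                start = "pinned", tip = "surface", sub = sub, n = n)
    fun <- function(lam, g) elastica_segment(robot, field_T * lam, seg,
                                             guess = g)
    sol <- continuation(fun, list(theta = rep(0, n + 1),
                                  F = robot$weight / 2))
    shp <- beam_shape(sol$s, x = sol$x, y = sol$y, footpads = robot$footpads)
    shp$theta <- sol$theta
    shp$dtheta_ds <- fd_deriv(sol$s, sol$theta)
    return(shp)
  }
  uf <- uf_for_chord(sub, d)
  st <- solve_attached_state(robot, sub, uf, field_T,
                             n_half = max(10L, round(n / 2)))
  shp <- attached_shape(robot, st)
  attr(shp, "F1") <- st$F1
  attr(shp, "F2") <- st$F2
  attr(shp, "patch_tension") <- st$tension
  shp
}

#' Internal bending moment along the body
#'
#' `M(s) = E I * dtheta/ds` with `I = w t^3 / 12`.
#'
#' @param shape a [beam_shape()].
#' @param robot a [robot_spec()].
#' @return vector of bending moments (N m) at the shape samples.
#' @export
bending_moment_profile <- function(shape, robot) {
  robot$EI * shape$dtheta_ds
}

#' Interface normal stress from the applied field
#'
#' In the dynamic small-deflection regime the robot-tissue interface normal
#' stress is proportional to the applied field:
#' \eqn{\sigma_{yy} = k_y B_y}. The scaling factor `ky` is a property of the
#' robot (magnetization profile and bulk modulus) obtained by calibration.
#'
#' @param By_mT field component (mT).
#' @param ky_Pa_per_mT calibrated stress scaling factor (Pa/mT).
#' @return normal stress (Pa).
#' @export
interface_stress <- function(By_mT, ky_Pa_per_mT) {
  ky_Pa_per_mT * By_mT
}
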