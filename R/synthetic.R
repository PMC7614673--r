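# Synthetic-data generators: forward-simulated detachment sequences,
# dynamic viscoelastic responses, particle sets and stiffness-inclusion
# substrates. Everything is seeded and reproducible; generators state the
# experimental world they emulate rather than exposing tuning dials.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Synthetic sensing scenario
#'
#' Bundles the robot, the substrate material, the actuation protocol and
#' the noise settings that define one emulated experiment.
#'
#' @param robot a [robot_spec()].
#' @param E_prime_Pa,E_dprime_Pa substrate storage / loss moduli (Pa).
#' @param Fa_N ground-truth patch adhesion (N).
#' @param curvature substrate signed curvature (1/m).
#' @param d_over_L footpad chord distance ratio of the attached
#'   configuration.
#' @param protocol a [detachment_protocol()] waveform (for detachment runs).
#' @param tracking_noise_px shape-tracking noise SD (pixels).
#' @param pixel_pitch_m imaging pixel pitch (m/px).
#' @param amplitude_noise_frac relative SD of the per-record strain
#'   amplitude jitter in dynamic runs.
#' @param seed RNG seed; fixed seed gives identical output.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(robot = robot_spec(),
                               E_prime_Pa = 3200, E_dprime_Pa = 500,
                               Fa_N = 0.5e-3, curvature = 0,
                               d_over_L = 0.75,
                               protocol = detachment_protocol(),
                               tracking_noise_px = 0,
                               pixel_pitch_m = 10e-6,
                               amplitude_noise_frac = 0,
                               seed = 1L) {
  stopifnot(E_prime_Pa > 0, E_dprime_Pa >= 0, Fa_N >= 0)
  structure(list(robot = robot, E_prime_Pa = E_prime_Pa,
                 E_dprime_Pa = E_dprime_Pa, Fa_N = Fa_N,
                 curvature = curvature, d_over_L = d_over_L,
                 protocol = protocol,
                 tracking_noise_px = tracking_noise_px,
                 pixel_pitch_m = pixel_pitch_m,
                 amplitude_noise_frac = amplitude_noise_frac,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Representative "just detached" frame: zero-field springback equilibrium,
# or a raised transient arch when the springback grazes the surface.
detached_frame_shape <- function(robot, sub, uf, min_clear = 1e-4) {
  dsol <- tryCatch(solve_detached_state(robot, sub, uf, c(0, 0)),
                   error = function(e) NULL)
  if (!is.null(dsol) &&
      abs(patch_clearance(dsol$shape, robot, sub)) >= min_clear)
    return(dsol$shape)
  g <- lobe_guess(robot$L, chord_of(sub, uf), 64, sign = +1)
  p0 <- sub$point(-uf)[1, ]
  shp <- beam_shape(seq(0, robot$L, length.out = 65), theta = g$theta,
                    origin = p0, footpads = robot$footpads)
  shp
}

# add seeded Gaussian tracking noise to a shape and retrack it
perturb_shape <- function(shape, sigma_m, footpads = attr(shape, "footpads")) {
  n <- nrow(shape)
  beam_shape(shape$s,
             x = shape$x + stats::rnorm(n, 0, sigma_m),
             y = shape$y + stats::rnorm(n, 0, sigma_m),
             smooth = TRUE, footpads = footpads)
}

#' Forward-simulate a detachment sequence
#'
#' Runs the load-step-detach protocol against the attached elastica model:
#' the patch stays fixed on the substrate while the pull-off demand
#' (tension) at the patch is below the ground-truth adhesion `Fa`, and the
#' robot snaps to the detached (footpads-pinned) equilibrium beyond it. The
#' exact threshold field where the demand equals `Fa` is located by
#' bisection inside the step interval and inserted as the last attached
#' frame, mimicking the quasi-static field ramp between staircase levels.
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_half elastica intervals per body half.
#' @return list with `shapes` (list of [beam_shape()]), `field`
#'   ([field_waveform()], one sample per frame), and `truth` (list:
#'   `Fa_N`, `B_detach_mT`, `threshold_index`, `detached`, `tension_mN`
#'   per frame).
#' @export
simulate_detachment_sequence <- function(scenario, n_half = 30) {
  if (scenario$protocol$kind != "load-step-detach")
    stop_magsense("scenario protocol must be load-step-detach",
                  "magsense_protocol_error")
  rb <- scenario$robot
  sub <- substrate(scenario$curvature)
  uf <- uf_for_chord(sub, scenario$d_over_L * rb$L)
  wf <- scenario$protocol
  Fa <- scenario$Fa_N

  shapes <- list(); times <- c(); Bx <- c(); By <- c(); tension <- c()
  st <- NULL; st_prev <- NULL
  threshold_index <- NA_integer_
  B_detach_mT <- NA_real_
  detached <- FALSE
  det_guess <- NULL

  for (i in seq_along(wf$time_s)) {
    B <- wf$B[i, ]
    if (!detached) {
      st_prev <- st
      st <- solve_attached_state(rb, sub, uf, B, state = st, n_half = n_half)
      if (st$tension > Fa) {
        # crossed inside this step: bisect the quasi-static ramp
        B_lo <- if (is.null(st_prev)) c(0, 0) else st_prev$field_T
        B_hi <- B
        st_b <- st
        for (k in 1:28) {
          Bm <- (B_lo + B_hi) / 2
          st_b <- solve_attached_state(rb, sub, uf, Bm, state = st_b,
                                       n_half = n_half)
          if (st_b$tension > Fa) B_hi <- Bm else B_lo <- Bm
          if (sum(abs(B_hi - B_lo)) < 1e-9) break
        }
        st_thr <- solve_attached_state(rb, sub, uf, B_lo, state = st_b,
                                       n_half = n_half)
        shapes <- c(shapes, list(attached_shape(rb, st_thr)))
        times <- c(times, wf$time_s[i] - 1e-3)
        Bx <- c(Bx, B_lo[1]); By <- c(By, B_lo[2])
        tension <- c(tension, st_thr$tension)
        threshold_index <- length(shapes)
        B_detach_mT <- sqrt(sum(B_lo^2)) * 1e3
        detached <- TRUE
        # Detached frame: the post-detachment transient is dynamic (the
        # freed body snaps through), outside the quasi-static model, so the
        # detached configuration is rendered at its zero-field springback;
        # if that springback grazes the surface (possible on convex bumps)
        # an explicit transient arch is used instead.
        shapes <- c(shapes, list(detached_frame_shape(rb, sub, uf)))
        times <- c(times, wf$time_s[i])
        Bx <- c(Bx, B[1]); By <- c(By, B[2])
        tension <- c(tension, NA)
        break
      }
      shapes <- c(shapes, list(attached_shape(rb, st)))
      tension <- c(tension, st$tension)
    }
    times <- c(times, wf$time_s[i])
    Bx <- c(Bx, B[1]); By <- c(By, B[2])
  }

  if (scenario$tracking_noise_px > 0) {
    sigma <- scenario$tracking_noise_px * scenario$pixel_pitch_m
    shapes <- with_seed(scenario$seed,
                        lapply(shapes, perturb_shape, sigma_m = sigma))
  }
  field <- field_waveform(times, Bx_mT = Bx * 1e3, By_mT = By * 1e3,
                          kind = "load-step-detach")
  list(shapes = shapes, field = field,
       truth = list(Fa_N = Fa, B_detach_mT = B_detach_mT,
                    threshold_index = threshold_index,
                    detached = detached, tension_N = tension,
                    d_over_L = scenario$d_over_L,
                    curvature = scenario$curvature))
}

#' Forward-simulate the dynamic interface strain response
#'
#' Generates per-frequency interface strain records under rotating fields
#' according to the calibrated forward law: mean-strain amplitude
#' `k (E')^a By` attenuated by the first-order response with
#' `tau = k_tau E'/E''`. The spatial profile is a single-period travelling
#' wave (following the magnetization phase) normalized so its central-window
#' mean reproduces the law; per-record amplitude jitter emulates
#' measurement noise.
#'
#' @param scenario a [synthetic_scenario()].
#' @param frequencies_hz sweep frequencies (Hz).
#' @param By_mT rotating-field magnitude (mT).
#' @param n_cycles full cycles per record (>= 4 by default).
#' @param samples_per_cycle time samples per cycle.
#' @param calibration forward-law constants, a [visco_calibration()].
#' @param n_s spatial samples along the body.
#' @return list of records: each has `time_s`, `frequency_hz`, `By_mT`,
#'   `eyy_mean`, `s`, `eyy` (space-time matrix, length(s) x length(time)),
#'   `amplitude_true`.
#' @export
simulate_dynamic_response <- function(scenario, frequencies_hz,
                                      By_mT = 20, n_cycles = 4,
                                      samples_per_cycle = 40,
                                      calibration = visco_calibration(),
                                      n_s = 65) {
  stopifnot(all(frequencies_hz > 0), By_mT >= 0)
  rb <- scenario$robot
  L <- rb$L
  tau <- if (scenario$E_dprime_Pa > 0)
    calibration$k_tau * scenario$E_prime_Pa / scenario$E_dprime_Pa else Inf
  A0 <- calibration$k * scenario$E_prime_Pa^calibration$a * By_mT
  s <- seq(0, L, length.out = n_s)
  # central-window mean of the travelling wave: reduction factor
  win_fac <- sin(0.4 * pi) / (0.4 * pi)
  with_seed(scenario$seed, {
    lapply(seq_along(frequencies_hz), function(j) {
      f <- frequencies_hz[j]
      w <- 2 * pi * f
      att <- if (is.finite(tau)) 1 / sqrt(1 + (w * tau)^2) else 1
      lag <- if (is.finite(tau)) atan(w * tau) else 0
      amp <- A0 * att
      amp_n <- amp * (1 + scenario$amplitude_noise_frac * stats::rnorm(1))
      tt <- seq(0, n_cycles / f, length.out = n_cycles * samples_per_cycle + 1)
      phase <- outer(-2 * pi * s / L, w * tt - lag, `+`)
      eyy <- (amp_n / win_fac) * sin(phase)
      eyy_mean <- vapply(seq_along(tt), function(k)
        mean_interface_strain(s, eyy[, k], L), 0)
      list(time_s = tt, frequency_hz = f, By_mT = By_mT,
           eyy_mean = eyy_mean, s = s, eyy = eyy,
           amplitude_true = amp)
    })
  })
}

#' Seed tracer particles and advect them through a displacement field
#'
#' @param region `c(xmin, xmax, ymin, ymax)` (m).
#' @param density_per_mm2 mean particle density (1/mm^2).
#' @param seed RNG seed.
#' @return `seed_particles`: object of class `particle_set`, a data frame
#'   with reference positions `x0`, `y0` (m) and current positions `x`,
#'   `y`.
#' @export
seed_particles <- function(region, density_per_mm2, seed = 1L) {
  stopifnot(length(region) == 4, density_per_mm2 > 0)
  wd <- region[2] - region[1]; ht <- region[4] - region[3]
  if (wd <= 0 || ht <= 0)
    stop_magsense("empty seeding region", "magsense_domain_error")
  area_mm2 <- wd * ht * 1e6
  with_seed(seed, {
    n <- stats::rpois(1, density_per_mm2 * area_mm2)
    x0 <- stats::runif(n, region[1], region[2])
    y0 <- stats::runif(n, region[3], region[4])
    structure(data.frame(id = seq_len(n), x0 = x0, y0 = y0, x = x0, y = y0),
              class = c("particle_set", "data.frame"))
  })
}

#' @rdname seed_particles
#' @param particles a `particle_set`.
#' @param displacement function `(x, y) -> list(ux, uy)` (m), evaluated at
#'   the reference positions.
#' @return `advect_particles`: the particle set with updated `x`, `y`.
#' @export
advect_particles <- function(particles, displacement) {
  u <- displacement(particles$x0, particles$y0)
  particles$x <- particles$x0 + u$ux
  particles$y <- particles$y0 + u$uy
  particles
}

#' Substrate stiffness map with an embedded stiff inclusion
#'
#' Heuristic forward model for distributed stiffness sensing: the local
#' interface deformation under a uniform load is taken proportional to the
#' reciprocal of the local storage modulus, smoothed by a Gaussian kernel
#' whose width equals the burial depth (deeper inclusions blur more). This
#' is not an elasticity solve; it generates profiles with the qualitative
#' signature the detector needs (reduced deformation over the stiff spot).
#'
#' @param background_E_Pa background storage modulus (Pa).
#' @param inclusion_E_Pa inclusion storage modulus (Pa), must exceed the
#'   background.
#' @param diameter_m inclusion diameter (m).
#' @param center_m inclusion centre along the profiled line (m).
#' @param depth_m burial depth (m), sets the smoothing kernel width.
#' @param span_m profiled span `c(min, max)` (m).
#' @return list with `E_map(x)` (Pa), and
#'   `deformation_profile(x, load_Pa = 1000)` returning the deformation
#'   magnitude (m) along positions `x`.
#' @export
make_inclusion_substrate <- function(background_E_Pa, inclusion_E_Pa,
                                     diameter_m, center_m, depth_m = 1e-3,
                                     span_m = c(0, 6.5e-3)) {
  if (inclusion_E_Pa <= background_E_Pa)
    stop_magsense("inclusion must be stiffer than the background",
                  "magsense_domain_error")
  if (center_m < span_m[1] || center_m > span_m[2])
    stop_magsense("inclusion outside the substrate span",
                  "magsense_domain_error")
  E_map <- function(x) ifelse(abs(x - center_m) <= diameter_m / 2,
                              inclusion_E_Pa, background_E_Pa)
  deformation_profile <- function(x, load_Pa = 1000) {
    # fine grid reciprocal-stiffness response, then depth smoothing
    xs <- seq(span_m[1] - 4 * depth_m, span_m[2] + 4 * depth_m,
              length.out = 801)
    resp <- load_Pa / E_map(xs)
    if (depth_m > 0) {
      dx <- xs[2] - xs[1]
      half <- ceiling(4 * depth_m / dx)
      kern <- stats::dnorm(seq(-half, half) * dx, sd = depth_m)
      kern <- kern / sum(kern)
      resp <- stats::filter(resp, kern, sides = 2)
      # edge fill
      resp[is.na(resp)] <- load_Pa / background_E_Pa
    }
    stats::approx(xs, as.numeric(resp), xout = x)$y
  }
  list(E_map = E_map, deformation_profile = deformation_profile,
       center_m = center_m, diameter_m = diameter_m, depth_m = depth_m,
       span_m = span_m)
}
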