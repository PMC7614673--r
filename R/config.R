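# Structured JSON configuration for robots, protocols and scenarios. All
# physical keys carry explicit unit suffixes to keep units honest at the
# file boundary.

#' Write / read a robot specification as JSON
#'
#' Keys carry unit suffixes (`L_mm`, `E_kPa`, `M0_kA_m`, ...). The
#' magnetization profile is stored either as the harmonic closed form
#' (`phase = "harmonic"` with `phase_offset_rad`) or as sampled vectors.
#'
#' @param robot a [robot_spec()].
#' @param path file path.
#' @export
write_robot_json <- function(robot, path) {
  mp <- robot$magnetization
  cfg <- list(
    L_mm = robot$L * 1e3, w_mm = robot$w * 1e3, t_mm = robot$t * 1e3,
    E_kPa = robot$E / 1e3, rho_g_cm3 = robot$rho / 1e3, Kr_Pa = robot$Kr,
    footpads_mm = robot$footpads * 1e3,
    patch_center_mm = robot$patch_center * 1e3,
    patch_length_mm = robot$patch_length * 1e3,
    M0_kA_m = mp$M0 / 1e3,
    phase = "harmonic")
  # store the phase offset implied at s = 0 relative to the plain harmonic
  cfg$phase_offset_rad <- mp$phi(0)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_robot_json
#' @return `read_robot_json`: a [robot_spec()].
#' @export
read_robot_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- cfg$L_mm * 1e-3
  off <- cfg$phase_offset_rad %||% (pi / 2)
  mp <- magnetization_profile(L, M0 = cfg$M0_kA_m * 1e3,
                              phase = function(s) 2 * pi * s / L + off)
  robot_spec(L = L, w = cfg$w_mm * 1e-3, t = cfg$t_mm * 1e-3,
             E = cfg$E_kPa * 1e3, rho = cfg$rho_g_cm3 * 1e3, Kr = cfg$Kr_Pa,
             magnetization = mp, footpads = cfg$footpads_mm * 1e-3,
             patch_center = cfg$patch_center_mm * 1e-3,
             patch_length = cfg$patch_length_mm * 1e-3)
}

#' Write / read a synthetic scenario as JSON
#'
#' @param scenario a [synthetic_scenario()].
#' @param path file path.
#' @export
write_scenario_json <- function(scenario, path) {
  pr <- scenario$protocol
  cfg <- list(
    E_prime_kPa = scenario$E_prime_Pa / 1e3,
    E_dprime_kPa = scenario$E_dprime_Pa / 1e3,
    Fa_mN = scenario$Fa_N * 1e3,
    curvature_per_m = scenario$curvature,
    d_over_L = scenario$d_over_L,
    tracking_noise_px = scenario$tracking_noise_px,
    pixel_pitch_um = scenario$pixel_pitch_m * 1e6,
    amplitude_noise_frac = scenario$amplitude_noise_frac,
    seed = scenario$seed,
    protocol = list(B_load_mT = pr$B_load_mT, dB_mT = pr$dB_mT,
                    step_dwell_s = pr$step_dwell_s, B_max_mT = pr$B_max_mT))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @param robot robot used by the scenario (stored separately).
#' @return `read_scenario_json`: a [synthetic_scenario()].
#' @export
read_scenario_json <- function(path, robot = robot_spec()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- cfg$protocol
  protocol <- detachment_protocol(B_load_mT = pr$B_load_mT %||% 13.4,
                                  dB_mT = pr$dB_mT %||% 2.7,
                                  step_dwell_s = pr$step_dwell_s %||% 2.5,
                                  B_max_mT = pr$B_max_mT %||% 40)
  synthetic_scenario(
    robot = robot,
    E_prime_Pa = (cfg$E_prime_kPa %||% 3.2) * 1e3,
    E_dprime_Pa = (cfg$E_dprime_kPa %||% 0.5) * 1e3,
    Fa_N = (cfg$Fa_mN %||% 0.5) * 1e-3,
    curvature = cfg$curvature_per_m %||% 0,
    d_over_L = cfg$d_over_L %||% 0.75,
    protocol = protocol,
    tracking_noise_px = cfg$tracking_noise_px %||% 0,
    pixel_pitch_m = (cfg$pixel_pitch_um %||% 10) * 1e-6,
    amplitude_noise_frac = cfg$amplitude_noise_frac %||% 0,
    seed = cfg$seed %||% 1L)
}

#' Write / read a field waveform as CSV
#'
#' Columns `time_s, Bx_mT, By_mT`.
#'
#' @param wf a [field_waveform()].
#' @param path file path.
#' @export
write_waveform_csv <- function(wf, path) {
  utils::write.csv(data.frame(time_s = wf$time_s,
                              Bx_mT = wf$B[, 1] * 1e3,
                              By_mT = wf$B[, 2] * 1e3),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param kind,frequency_hz waveform metadata not stored in the CSV.
#' @export
read_waveform_csv <- function(path, kind = "custom", frequency_hz = NULL) {
  df <- utils::read.csv(path)
  field_waveform(df$time_s, Bx_mT = df$Bx_mT, By_mT = df$By_mT,
                 kind = kind, frequency_hz = frequency_hz)
}

#' Write / read a viscoelastic calibration as JSON
#' @param calibration a [visco_calibration()].
#' @param path file path.
#' @export
write_calibration_json <- function(calibration, path) {
  jsonlite::write_json(list(k_Pa_per_mT = calibration$k, a = calibration$a,
                            k_tau_s = calibration$k_tau),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  visco_calibration(k = cfg$k_Pa_per_mT, a = cfg$a, k_tau = cfg$k_tau_s)
}
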