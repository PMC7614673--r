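# Dynamic viscoelastic sensing: mean interface strain, power-law
# storage-modulus calibration, frequency-sweep time constant, loss modulus.
#
# Model: under a rotating field of y-amplitude By (mT), the amplitude of the
# mean interface strain follows the calibrated power law
#   amp(eyy_mean) / By = k * (E')^a        (k in Pa/mT, a < 0)
# attenuated at frequency omega by a first-order response
#   A(omega) = A0 / sqrt(1 + (omega*tau)^2),
# with the material time constant linked to the moduli by tau = k_tau*E'/E''.

#' Viscoelastic calibration constants
#'
#' @param k power-law scale factor (Pa/mT); printed calibration 54.128.
#' @param a power-law exponent (dimensionless, negative); printed -1.067.
#' @param k_tau time-constant ratio (s), `tau = k_tau * E' / E''`; printed
#'   0.0703 s.
#' @param training optional data frame of training-material records.
#' @return object of class `visco_calibration`.
#' @export
visco_calibration <- function(k = 54.128, a = -1.067, k_tau = 0.0703,
                              training = NULL) {
  if (!(is_number(k) && k > 0 && is_number(a) && a < 0 &&
        is_number(k_tau) && k_tau > 0))
    stop_magsense("need k > 0, a < 0, k_tau > 0", "magsense_domain_error")
  structure(list(k = k, a = a, k_tau = k_tau, training = training),
            class = "visco_calibration")
}

#' Mean interface strain over the central 40% of the body
#'
#' \eqn{\bar\epsilon_{yy} = \int_{0.3L}^{0.7L} \epsilon_{yy}(s)\,ds / 0.4L},
#' the central window being where the interface signal-to-noise ratio is
#' highest.
#'
#' @param s material coordinates (m) of the strain samples.
#' @param eyy normal strain at `s`.
#' @param L body length (m).
#' @return scalar mean strain.
#' @export
mean_interface_strain <- function(s, eyy, L) {
  lo <- 0.3 * L; hi <- 0.7 * L
  if (min(s) > lo + 1e-12 || max(s) < hi - 1e-12)
    stop_magsense("strain profile does not cover [0.3L, 0.7L]",
                  "magsense_domain_error")
  keep <- s >= lo - 1e-12 & s <= hi + 1e-12
  si <- s[keep]; ei <- eyy[keep]
  # close the window ends exactly by interpolation
  if (min(si) > lo) { si <- c(lo, si); ei <- c(stats::approx(s, eyy, lo)$y, ei) }
  if (max(si) < hi) { si <- c(si, hi); ei <- c(ei, stats::approx(s, eyy, hi)$y) }
  trapz(si, ei) / (0.4 * L)
}

#' Oscillation amplitude of a mean-strain series
#'
#' Half the peak-to-peak excursion over whole actuation cycles. The series
#' is phase-folded on the waveform frequency and averaged in phase bins
#' before taking the peak-to-peak, which suppresses sample noise; cycle
#' boundaries come from the waveform, not from the signal.
#'
#' @param time_s time stamps (s).
#' @param eyy_mean mean-strain series.
#' @param frequency_hz actuation frequency (Hz).
#' @param n_bins phase bins for folding.
#' @return scalar amplitude.
#' @export
amplitude_of <- function(time_s, eyy_mean, frequency_hz, n_bins = 32) {
  span <- diff(range(time_s))
  if (span * frequency_hz < 2 - 1e-9)
    stop_magsense("need at least two full actuation cycles",
                  "magsense_insufficient_data")
  n_cyc <- floor(span * frequency_hz + 1e-9)
  keep <- time_s <= min(time_s) + n_cyc / frequency_hz + 1e-12
  tt <- time_s[keep]; yy <- eyy_mean[keep]
  ph <- ((tt - tt[1]) * frequency_hz) %% 1
  bins <- pmin(floor(ph * n_bins) + 1L, n_bins)
  folded <- tapply(yy, bins, mean)
  (max(folded) - min(folded)) / 2
}

#' Fit the power-law storage-modulus calibration
#'
#' Least-squares line in log-log space through training pairs
#' `(E', amp/By)`, returning the scale `k` (Pa/mT) and exponent `a`.
#'
#' @param E_prime_Pa storage moduli of training materials (Pa).
#' @param amp_per_By strain amplitude per field (1/mT).
#' @return a [visco_calibration()] with fitted `k`, `a` (default `k_tau`).
#' @export
fit_calibration <- function(E_prime_Pa, amp_per_By) {
  if (length(E_prime_Pa) < 2 || length(unique(E_prime_Pa)) < 2)
    stop_magsense("need >= 2 distinct E' values", "magsense_domain_error")
  if (any(E_prime_Pa <= 0) || any(amp_per_By <= 0))
    stop_magsense("calibration inputs must be positive", "magsense_domain_error")
  fit <- stats::lm(log(amp_per_By) ~ log(E_prime_Pa))
  a <- unname(stats::coef(fit)[2])
  k <- exp(unname(stats::coef(fit)[1]))
  visco_calibration(k = k, a = a)
}

#' Storage modulus from a low-frequency strain amplitude
#'
#' Inverts the power law: `E' = (amp / (By * k))^(1/a)`.
#'
#' @param amplitude mean-strain amplitude (dimensionless).
#' @param By_mT field amplitude (mT).
#' @param calibration a [visco_calibration()].
#' @return storage modulus E' (Pa).
#' @export
estimate_storage_modulus <- function(amplitude, By_mT, calibration) {
  if (!(is_number(amplitude) && amplitude > 0 && is_number(By_mT) && By_mT > 0))
    stop_magsense("amplitude and By must be positive", "magsense_domain_error")
  (amplitude / (By_mT * calibration$k))^(1 / calibration$a)
}

#' Time constant from a frequency sweep
#'
#' Fits the first-order amplitude response
#' \eqn{A(\omega) = A_0/\sqrt{1 + (\omega\tau)^2}} to per-frequency
#' amplitudes by least squares. If the amplitudes do not decrease with
#' frequency the fit is degenerate and `tau = 0` is returned with a
#' warning.
#'
#' @param frequency_hz sweep frequencies (Hz), >= 2 distinct values.
#' @param amplitude strain amplitudes at those frequencies.
#' @return list with `tau_s`, `A0`, `fitted`.
#' @export
fit_time_constant <- function(frequency_hz, amplitude) {
  o <- order(frequency_hz)
  f <- frequency_hz[o]; A <- amplitude[o]
  if (length(unique(f)) < 2)
    stop_magsense("need >= 2 distinct frequencies", "magsense_domain_error")
  degen <- stats::sd(A) == 0 || stats::cor(f, A) >= 0 || A[length(A)] >= A[1]
  if (degen) {
    warn_magsense("amplitudes do not roll off with frequency; tau = 0",
                  "magsense_fit_degenerate")
    return(list(tau_s = 0, A0 = mean(A), fitted = rep(mean(A), length(A))))
  }
  w <- 2 * pi * f
  # closed-form two-point start from the extreme frequencies
  r2 <- (A[1] / A[length(A)])^2
  tau0 <- sqrt(max((r2 - 1), 1e-6) /
                 max(w[length(w)]^2 - r2 * w[1]^2, 1e-12))
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- 1 / w[length(w)]
  obj <- function(p) {
    A0 <- exp(p[1]); tau <- exp(p[2])
    sum((A - A0 / sqrt(1 + (w * tau)^2))^2)
  }
  fit <- stats::optim(c(log(A[1]), log(tau0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  A0 <- exp(fit$par[1]); tau <- exp(fit$par[2])
  list(tau_s = tau, A0 = A0, fitted = A0 / sqrt(1 + (w * tau)^2))
}

#' Loss modulus from the time constant
#'
#' `E'' = k_tau * E' / tau`. A vanishing `tau` flags a purely elastic
#' response (`E'' = 0`).
#'
#' @param E_prime_Pa storage modulus (Pa).
#' @param tau_s time constant (s).
#' @param calibration a [visco_calibration()].
#' @return list with `E_dprime_Pa` and `purely_elastic`.
#' @export
estimate_loss_modulus <- function(E_prime_Pa, tau_s, calibration) {
  if (!(is_number(E_prime_Pa) && E_prime_Pa > 0))
    stop_magsense("E' must be positive", "magsense_domain_error")
  if (tau_s <= 0)
    return(list(E_dprime_Pa = 0, purely_elastic = TRUE))
  list(E_dprime_Pa = calibration$k_tau * E_prime_Pa / tau_s,
       purely_elastic = FALSE)
}

#' Full frequency-sweep viscoelasticity pipeline
#'
#' Takes one mean-strain record per sweep frequency, extracts amplitudes,
#' anchors the storage modulus at the low-frequency (0.1 Hz) record,
#' extracts the time constant from the roll-off and derives the loss
#' modulus. The 0.1 Hz anchor is corrected for its own (usually tiny)
#' first-order attenuation using the fitted time constant, iterated once to
#' convergence.
#'
#' @param records list of records, each a list with `time_s`, `eyy_mean`,
#'   `frequency_hz`, `By_mT`.
#' @param calibration a [visco_calibration()].
#' @param anchor_hz low-frequency anchor (Hz).
#' @return object of class `visco_estimate`: `E_prime_Pa`, `E_dprime_Pa`,
#'   `tau_s`, `purely_elastic`, and `table` (data frame of
#'   `frequency_hz`, `amplitude`, `By_mT`).
#' @export
run_viscoelastic_pipeline <- function(records, calibration = visco_calibration(),
                                      anchor_hz = 0.1) {
  freqs <- vapply(records, `[[`, 0, "frequency_hz")
  if (!any(abs(freqs - anchor_hz) < 1e-9))
    stop_magsense(sprintf("missing %g Hz low-frequency anchor record", anchor_hz),
                  "magsense_protocol_error")
  if (length(freqs) < 3)
    stop_magsense("need the anchor plus >= 2 higher frequencies",
                  "magsense_protocol_error")
  amp <- vapply(records, function(r)
    amplitude_of(r$time_s, r$eyy_mean, r$frequency_hz), 0)
  By <- vapply(records, `[[`, 0, "By_mT")
  tab <- data.frame(frequency_hz = freqs, amplitude = amp, By_mT = By)
  tab <- tab[order(tab$frequency_hz), ]
  ia <- which.min(abs(tab$frequency_hz - anchor_hz))
  # normalize amplitudes by field so mixed-By sweeps are comparable
  rel <- tab$amplitude / tab$By_mT
  ft <- suppressWarnings(fit_time_constant(tab$frequency_hz, rel))
  A_anchor <- tab$amplitude[ia]
  E_prime <- estimate_storage_modulus(A_anchor, tab$By_mT[ia], calibration)
  for (i in 1:2) {  # correct the anchor for its own attenuation
    corr <- sqrt(1 + (2 * pi * anchor_hz * ft$tau_s)^2)
    E_prime <- estimate_storage_modulus(A_anchor * corr, tab$By_mT[ia],
                                        calibration)
  }
  lm <- estimate_loss_modulus(E_prime, ft$tau_s, calibration)
  structure(list(E_prime_Pa = E_prime, E_dprime_Pa = lm$E_dprime_Pa,
                 tau_s = ft$tau_s, purely_elastic = lm$purely_elastic,
                 table = tab),
            class = "visco_estimate")
}

#' @export
print.visco_estimate <- function(x, ...) {
  cat(sprintf(
    "<visco_estimate> E' = %.3g kPa  E'' = %.3g kPa  tau = %.3g s%s\n",
    x$E_prime_Pa / 1e3, x$E_dprime_Pa / 1e3, x$tau_s,
    if (x$purely_elastic) " (purely elastic)" else ""))
  invisible(x)
}

#' Read / write sweep records as CSV
#'
#' Long format with columns `time_s, frequency_hz, By_mT, eyy_mean`.
#'
#' @param records list of sweep records (see
#'   [run_viscoelastic_pipeline()]).
#' @param path file path.
#' @export
write_sweep_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r)
    data.frame(time_s = r$time_s, frequency_hz = r$frequency_hz,
               By_mT = r$By_mT, eyy_mean = r$eyy_mean)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$frequency_hz), function(d)
    list(time_s = d$time_s, eyy_mean = d$eyy_mean,
         frequency_hz = d$frequency_hz[1], By_mT = d$By_mT[1]))
}

#' Write a viscoelastic estimate as JSON
#' @param est a `visco_estimate`.
#' @param path output file.
#' @export
write_visco_json <- function(est, path) {
  jsonlite::write_json(
    list(E_prime_Pa = est$E_prime_Pa, E_dprime_Pa = est$E_dprime_Pa,
         tau_s = est$tau_s, purely_elastic = est$purely_elastic,
         table = est$table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
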