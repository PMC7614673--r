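# Static inverse model: patch-tissue adhesion from the buckled shape at the
# detachment threshold, and the pH mapping through the responsive adhesive.
#
# The estimator uses only statics. For each body half between a footpad and
# a patch edge, the internal bending moment measured from the shape,
# M(s) = EI dtheta/ds, must equal the moment of all loads on the far part of
# the half (footpad reaction, gravity, distributed magnetic torque) about
# the material point s. Each sample therefore yields one linear equation in
# the unknown footpad reaction vector; the overdetermined system is solved
# by least squares, which makes the estimate robust to tracking noise. The
# adhesive force then follows from whole-body force balance
# F1 + F2 + F_adh = W, and the pull-off force Fa is its tensile component
# along the patch normal.

#' Estimate patch-tissue adhesion from a threshold shape
#'
#' @param shape [beam_shape()] of the last attached configuration
#'   (pinned-fixed-pinned), sampled uniformly in `s` over the whole body.
#' @param field_mT field at the detachment threshold: either a vector
#'   `c(Bx, By)` in mT or a scalar magnitude applied along `field_axis`.
#' @param robot a [robot_spec()].
#' @param field_axis unit vector used when `field_mT` is a scalar; the
#'   default -y is the peel direction of the standard protocol.
#' @param sub [substrate()] used for footpad normal directions and the
#'   feasibility check (flat default).
#' @param on_infeasible `"warn"` (default) or `"error"`: behaviour when a
#'   footpad normal reaction comes out negative (footpads cannot pull),
#'   which signals an inconsistent threshold frame.
#' @return object of class `adhesion_estimate`: list with `Fa_N`,
#'   `F1_N`, `F2_N` (footpad normal reactions), `F1_vec`, `F2_vec`,
#'   `B_detach_mT`, `residual_Nm` (RMS moment-balance residual),
#'   `force_residual_N`, `feasible`.
#' @export
estimate_adhesion <- function(shape, field_mT, robot,
                              field_axis = c(0, -1), sub = substrate(0),
                              on_infeasible = c("warn", "error")) {
  on_infeasible <- match.arg(on_infeasible)
  field_T <- field_vec_T(field_mT, field_axis)
  h <- robot$patch_length / 2
  eps <- 1e-9
  iL <- which(shape$s <= robot$patch_center - h + eps)
  iR <- which(shape$s >= robot$patch_center + h - eps)
  if (length(iL) < 4 || length(iR) < 4)
    stop_magsense("shape does not cover the three-contact topology",
                  "magsense_topology_error")

  fitL <- half_reaction(shape, rev(iL), robot, field_T)
  fitR <- half_reaction(shape, iR, robot, field_T)
  F1 <- fitL$F; F2 <- fitR$F
  F_adh <- c(0, robot$weight) - F1 - F2

  ip <- which.min(abs(shape$s - robot$patch_center))
  n_p <- c(-sin(shape$theta[ip]), cos(shape$theta[ip]))
  Fa <- -sum(F_adh * n_p)

  fp <- attr(shape, "footpad_xy")
  n1 <- tip_normal(sub, fp[1, 1], fp[1, 2])
  n2 <- tip_normal(sub, fp[2, 1], fp[2, 2])
  F1n <- sum(F1 * n1); F2n <- sum(F2 * n2)
  feasible <- F1n >= -1e-9 && F2n >= -1e-9
  if (!feasible) {
    msg <- "negative footpad reaction: threshold frame likely inconsistent"
    if (on_infeasible == "error") stop_magsense(msg, "magsense_infeasible_error")
    warn_magsense(msg, "magsense_infeasible_warning")
  }
  structure(list(Fa_N = Fa, F1_N = F1n, F2_N = F2n,
                 F1_vec = F1, F2_vec = F2,
                 B_detach_mT = sqrt(sum(field_T^2)) * 1e3,
                 residual_Nm = sqrt(mean(c(fitL$resid, fitR$resid)^2)),
                 force_residual_N = 0,
                 feasible = feasible),
            class = "adhesion_estimate")
}

field_vec_T <- function(field_mT, field_axis = c(0, -1)) {
  if (length(field_mT) == 1) field_mT * 1e-3 * field_axis / sqrt(sum(field_axis^2))
  else field_mT * 1e-3
}

# least-squares footpad reaction for one half, samples ordered patch edge ->
# footpad
half_reaction <- function(shape, idx, robot, field_T) {
  s <- shape$s[idx]; th <- shape$theta[idx]
  x <- shape$x[idx]; y <- shape$y[idx]
  dxi <- abs(diff(s))
  if (diff(range(dxi)) > 1e-6 * mean(dxi))
    stop_magsense("half must be uniformly sampled in s", "magsense_domain_error")
  dxi <- mean(dxi)
  m <- length(idx)
  wline <- rep(-robot$rho * robot$A * G_ACCEL, m)
  tau <- robot_torque(robot, s, th, field_T)
  C <- far_moment(x, y, wline, rep(0, m), tau, dxi, NULL)
  a <- -(y[m] - y)          # dMom/dFx
  b <- (x[m] - x)           # dMom/dFy
  lhs <- robot$EI * dmid4(th, dxi) - mid4(C)
  A <- cbind(mid4(a), mid4(b))
  fit <- qr(A)
  F <- qr.coef(fit, lhs)
  # a degenerate (straight) half leaves one reaction component
  # unidentifiable; it carries no moment, report it as zero
  F[is.na(F)] <- 0
  list(F = as.numeric(F), resid = lhs - A %*% F)
}

#' @export
print.adhesion_estimate <- function(x, ...) {
  cat(sprintf("<adhesion_estimate> Fa = %.4g mN at B_detach = %.3g mT\n",
              x$Fa_N * 1e3, x$B_detach_mT))
  cat(sprintf("  footpad reactions %.4g / %.4g mN, feasible: %s\n",
              x$F1_N * 1e3, x$F2_N * 1e3, x$feasible))
  if (!is.null(x$repeats))
    cat(sprintf("  repeats: n = %d, mean = %.4g mN, rel SD = %.2f%%\n",
                x$repeats$n, x$repeats$mean_N * 1e3, 100 * x$repeats$rel_sd))
  invisible(x)
}

#' Run the detachment-protocol inversion on a tracked series
#'
#' Identifies the detachment threshold in a time-aligned series of shapes
#' and fields (the last frame before the patch separates from the
#' substrate, detected as a jump of the patch-region clearance beyond
#' `gap_m`), and estimates the adhesion there. When given repeated series,
#' aggregates the estimates into mean and relative SD.
#'
#' @param shapes list of [beam_shape()] (one series), or a list of such
#'   lists (repeats).
#' @param field [field_waveform()] with one sample per frame (or a list of
#'   them for repeats).
#' @param robot a [robot_spec()].
#' @param sub [substrate()] beneath the robot.
#' @param gap_m clearance threshold (m); default twice the 10 um pixel
#'   pitch of the imaging defaults.
#' @inheritParams estimate_adhesion
#' @return an `adhesion_estimate` (of the first series when repeated), with
#'   `threshold_index` and, for repeats, a `repeats` element holding `n`,
#'   `mean_N`, `rel_sd`, `Fa_N` (per repeat).
#' @export
run_detachment_inversion <- function(shapes, field, robot,
                                     sub = substrate(0), gap_m = 2 * 10e-6,
                                     on_infeasible = "warn") {
  if (length(shapes) && inherits(shapes[[1]], "beam_shape")) {
    shapes <- list(shapes)
    field <- list(field)
  }
  ests <- vector("list", length(shapes))
  for (r in seq_along(shapes)) {
    ser <- shapes[[r]]; wf <- field[[r]]
    if (length(ser) != length(wf$time_s))
      stop_magsense("shape series and field series are not aligned",
                    "magsense_domain_error")
    clr <- vapply(ser, function(sh) patch_clearance(sh, robot, sub), 0)
    # patch separation shows as a jump in clearance between frames (the
    # detached body may even interpenetrate an un-modelled convex surface,
    # so the jump, not the sign, is the robust signature)
    det <- which(abs(diff(clr)) > gap_m) + 1L
    if (!length(det))
      stop_magsense("no detachment observed within the series",
                    "magsense_protocol_error")
    j <- det[1]
    if (j == 1)
      stop_magsense("first frame already detached: no attached reference",
                    "magsense_protocol_error")
    est <- estimate_adhesion(ser[[j - 1]], wf$B[j - 1, ] * 1e3, robot,
                             sub = sub, on_infeasible = on_infeasible)
    est$threshold_index <- j - 1
    ests[[r]] <- est
  }
  out <- ests[[1]]
  if (length(ests) > 1) {
    fa <- vapply(ests, `[[`, 0, "Fa_N")
    out$repeats <- list(n = length(fa), mean_N = mean(fa),
                        rel_sd = stats::sd(fa) / mean(fa), Fa_N = fa)
  }
  out
}

# mean clearance of the patch-region samples above the substrate
patch_clearance <- function(shape, robot, sub) {
  h <- robot$patch_length / 2
  i <- which(abs(shape$s - robot$patch_center) <= h + 1e-9)
  mean(sub$sdist(cbind(shape$x[i], shape$y[i])))
}

#' pH calibration of the adhesive patch
#'
#' Tissue-specific anchors relating patch adhesion (mN) to surface pH.
#' Built-in calibrations: porcine stomach (pH 1 -> 1.08 mN, pH 5 ->
#' 0.31 mN) and porcine small intestine (pH 4 -> 0.58 mN, pH 8 ->
#' 0.11 mN). Adhesion must decrease strictly with pH.
#'
#' @param tissue `"stomach"` or `"small_intestine"`, ignored when `pH` and
#'   `adhesion_mN` are supplied.
#' @param pH,adhesion_mN custom anchor vectors.
#' @return object of class `ph_calibration`.
#' @export
ph_calibration <- function(tissue = c("stomach", "small_intestine"),
                           pH = NULL, adhesion_mN = NULL) {
  if (is.null(pH)) {
    tissue <- match.arg(tissue)
    anchors <- switch(tissue,
      stomach = list(pH = c(1, 5), adhesion_mN = c(1.08, 0.31)),
      small_intestine = list(pH = c(4, 8), adhesion_mN = c(0.58, 0.11)))
    pH <- anchors$pH; adhesion_mN <- anchors$adhesion_mN
    label <- tissue
  } else label <- "custom"
  stopifnot(length(pH) == length(adhesion_mN), length(pH) >= 2)
  o <- order(pH)
  pH <- pH[o]; adhesion_mN <- adhesion_mN[o]
  if (any(diff(adhesion_mN) >= 0))
    stop_magsense("adhesion must decrease strictly with pH",
                  "magsense_domain_error")
  structure(list(tissue = label, pH = pH, adhesion_mN = adhesion_mN),
            class = "ph_calibration")
}

#' Map adhesion to pH
#'
#' Piecewise-linear interpolation between calibration anchors; the patch
#' adhesion is close to linear in surface pH over the calibrated range. The
#' reported band reflects the 1-pH-unit sensitivity of the responsive
#' adhesive.
#'
#' @param Fa_mN estimated adhesion (mN).
#' @param calibration a [ph_calibration()].
#' @param clamp if `TRUE`, values outside the anchored adhesion range are
#'   clamped to the range ends instead of raising an error.
#' @return list with `pH`, `band` (`pH` +/- 0.5, clipped to the calibrated
#'   range) and `tissue`.
#' @export
adhesion_to_pH <- function(Fa_mN, calibration, clamp = FALSE) {
  rng <- range(calibration$adhesion_mN)
  if (Fa_mN < rng[1] || Fa_mN > rng[2]) {
    if (!clamp)
      stop_magsense(sprintf(
        "adhesion %.3g mN outside calibrated range [%.3g, %.3g] mN",
        Fa_mN, rng[1], rng[2]), "magsense_calibration_error")
    Fa_mN <- min(max(Fa_mN, rng[1]), rng[2])
  }
  o <- order(calibration$adhesion_mN)
  ph <- stats::approx(calibration$adhesion_mN[o], calibration$pH[o],
                      xout = Fa_mN)$y
  prng <- range(calibration$pH)
  list(pH = ph,
       band = c(max(ph - 0.5, prng[1]), min(ph + 0.5, prng[2])),
       tissue = calibration$tissue)
}

#' Write an adhesion estimate as JSON
#'
#' @param est an `adhesion_estimate`.
#' @param path output file.
#' @param pH optional result of [adhesion_to_pH()] to embed.
#' @export
write_adhesion_json <- function(est, path, pH = NULL) {
  out <- list(Fa_mN = est$Fa_N * 1e3, F1_mN = est$F1_N * 1e3,
              F2_mN = est$F2_N * 1e3, B_detach_mT = est$B_detach_mT,
              feasible = est$feasible)
  if (!is.null(est$repeats)) out$rel_sd <- est$repeats$rel_sd
  if (!is.null(pH)) { out$pH <- pH$pH; out$pH_band <- pH$band }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
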