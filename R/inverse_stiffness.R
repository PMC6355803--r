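#' Internal axial trunk moment from observed kinematics
#'
#' Single-segment inverse dynamics of the thorax: the net internal trunk
#' moment is the moment required by the observed thorax angular acceleration
#' after removing the arm-swing contribution,
#' `M_trunk(t) = I * thorax_acc(t) - M_arm(t)`, with the acceleration
#' obtained by double central differencing of the (optionally low-pass
#' filtered) thorax angle in radians. On data generated by the forward model
#' this equals the spring-damper moment by the equation of motion.
#'
#' @param rec A [trajectory_recording()] with thorax and arm-moment series.
#' @param inertia Thorax axial inertia, kg m^2.
#' @param lowpass_cutoff Zero-phase low-pass cutoff (Hz) applied before
#'   differentiation; `NULL` disables filtering.
#' @return Internal trunk moment series, Nm.
#' @export
trunk_moment_from_kinematics <- function(rec, inertia, lowpass_cutoff = 10) {
  validate_recording(rec)
  if (is.null(rec$thorax_angle)) stop("recording has no thorax_angle series")
  if (is.null(rec$arm_moment)) stop("recording has no arm_moment series")
  if (!is.finite(inertia) || inertia <= 0) stop("inertia must be > 0")
  fs <- rec$sample_rate
  th <- rec$thorax_angle * pi / 180
  if (!is.null(lowpass_cutoff)) th <- lowpass_filter(th, fs, lowpass_cutoff)
  acc <- differentiate(th, fs, order = 2)
  inertia * acc - rec$arm_moment
}

#' Stiffness as the slope of the moment-angle regression
#'
#' Ordinary least-squares regression of the negated internal trunk moment on
#' the trunk (thorax minus pelvis) angle, so a restoring spring yields a
#' positive slope in Nm/rad. Over whole cycles of near-sinusoidal motion the
#' damping moment is orthogonal to the angle and does not bias the slope.
#'
#' @param moment Internal trunk moment, Nm.
#' @param trunk_angle Thorax minus pelvis angle, radians.
#' @return A list with `slope` (Nm/rad), `intercept` (Nm) and `fit_r2` (%).
#' @export
stiffness_from_regression <- function(moment, trunk_angle) {
  if (length(moment) != length(trunk_angle))
    stop("moment and trunk_angle must have the same length")
  if (length(moment) < 3) stop("need at least 3 samples")
  if (var(trunk_angle) == 0) stop("trunk_angle has zero variance; slope is undefined")
  fit <- lm(y ~ x, data = data.frame(x = trunk_angle, y = -moment))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fit_r2 = 100 * summary(fit)$r.squared)
}

#' Compare forward-dynamic and inverse-dynamics stiffness estimates
#'
#' @param forward,inverse Equal-length vectors (>= 3) of per-subject
#'   stiffness estimates, Nm/rad.
#' @param subject_id Optional subject labels.
#' @return An object of class `stiffness_comparison` with the per-subject
#'   `pairs` table, `common_variance` (100 r^2, %), its `p_value`, and
#'   `rmse` between the methods (Nm/rad). Common variance and RMSE are both
#'   symmetric in the two methods.
#' @export
compare_estimators <- function(forward, inverse, subject_id = NULL) {
  if (length(forward) != length(inverse))
    stop("forward and inverse must have the same length")
  if (length(forward) < 3) stop("need at least 3 subjects")
  ct <- cor.test(forward, inverse)
  structure(list(
    pairs = data.frame(
      subject_id = if (is.null(subject_id)) seq_along(forward) else subject_id,
      forward_Nm_per_rad = forward, inverse_Nm_per_rad = inverse),
    common_variance = 100 * unname(ct$estimate)^2,
    p_value = ct$p.value,
    rmse = sqrt(mean((forward - inverse)^2))
  ), class = "stiffness_comparison")
}

#' @export
print.stiffness_comparison <- function(x, ...) {
  cat(sprintf("<stiffness_comparison> n = %d\n", nrow(x$pairs)))
  cat(sprintf("  common variance %.1f%% (p = %.3g), RMSE %.2f Nm/rad\n",
              x$common_variance, x$p_value, x$rmse))
  invisible(x)
}

#' Export a stiffness comparison as CSV plus summary JSON
#'
#' @param cmp A `stiffness_comparison`.
#' @param csv_path Per-subject pairs CSV path.
#' @param json_path Summary JSON path (`common_variance_pct, rmse_Nm_per_rad`).
#' @return `cmp`, invisibly.
#' @export
write_stiffness_comparison <- function(cmp, csv_path, json_path) {
  write.csv(cmp$pairs, csv_path, row.names = FALSE)
  jsonlite::write_json(list(common_variance_pct = cmp$common_variance,
                            p_value = cmp$p_value,
                            rmse_Nm_per_rad = cmp$rmse),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(cmp)
}
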