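#' Simulate the effect of scaled stiffness or arm-swing moment on coordination
#'
#' Re-runs the forward-dynamic model for a set of multiplication factors
#' applied either to the trunk stiffness (damping is never scaled) or to the
#' arm-swing moment series, keeping everything else fixed, and evaluates the
#' pelvis-to-thorax frequency response at the stride frequency of the
#' (unchanged) pelvis series — so all factors are compared at the same
#' frequency bin. The first `transient` seconds of each simulation are
#' discarded before the frequency response is evaluated.
#'
#' @param rec A [trajectory_recording()] with pelvis and arm-moment series.
#' @param params Fitted (or ground-truth) [trunk_model_params()] used as the
#'   baseline.
#' @param target `"stiffness"` or `"arm_moment"`.
#' @param factors Multiplication factors; 1.0 is added as the baseline anchor
#'   if absent, and the set is sorted increasing.
#' @param transient Seconds discarded from the start before evaluating the
#'   frequency response (capped at 20% of the record).
#' @param lowpass_cutoff Optional pelvis filter cutoff passed to
#'   [simulate_thorax()].
#' @return An object of class `coordination_sweep` with `target`, `factors`,
#'   `phase_by_factor` (deg), `gain_by_factor`, `stride_frequency`,
#'   `baseline_params` and `subject_id`. `as.data.frame()` yields the
#'   long-format table `subject_id, target, factor, relative_phase_deg, gain`.
#' @export
sweep_coordination <- function(rec, params,
                               target = c("stiffness", "arm_moment"),
                               factors = c(0.5, 0.75, 1, 1.25, 1.5),
                               transient = 10, lowpass_cutoff = NULL) {
  target <- match.arg(target)
  validate_recording(rec)
  stopifnot(inherits(params, "trunk_model_params"))
  if (is.null(rec$arm_moment))
    stop("recording has no arm_moment series; cannot sweep")
  if (length(factors) == 0) stop("factors must be a non-empty numeric vector")
  if (!all(is.finite(factors)) || any(factors <= 0))
    stop("factors must be positive finite multipliers")
  factors <- sort(unique(c(factors, 1)))

  fs <- rec$sample_rate
  deg2rad <- pi / 180
  pelvis <- rec$pelvis_angle * deg2rad
  pelvis_f <- if (is.null(lowpass_cutoff)) pelvis
              else lowpass_filter(pelvis, fs, lowpass_cutoff)
  pelvis_vel <- differentiate(pelvis_f, fs)
  init <- c(pelvis_f[1], pelvis_vel[1])

  duration <- rec$time[length(rec$time)] - rec$time[1]
  transient <- min(transient, 0.2 * duration)
  keep <- rec$time >= rec$time[1] + transient
  f0 <- stride_frequency(rec$pelvis_angle[keep], fs)

  phase <- gain <- numeric(length(factors))
  for (i in seq_along(factors)) {
    a <- factors[i]
    k <- if (target == "stiffness") a * params$stiffness else params$stiffness
    arm <- if (target == "arm_moment") a * rec$arm_moment else rec$arm_moment
    thorax <- rk4_trunk(k, params$damping, params$inertia, pelvis_f,
                        pelvis_vel, arm, 1 / fs, init[1], init[2])
    frf <- frf_at_frequency(rec$pelvis_angle[keep], thorax[keep] / deg2rad, fs, f0)
    phase[i] <- frf$relative_phase
    gain[i] <- frf$gain
  }
  structure(list(target = target, factors = factors, phase_by_factor = phase,
                 gain_by_factor = gain, stride_frequency = f0,
                 baseline_params = params, subject_id = rec$subject_id),
            class = "coordination_sweep")
}

#' @export
print.coordination_sweep <- function(x, ...) {
  cat(sprintf("<coordination_sweep> subject %s, target %s (f0 = %.3f Hz)\n",
              x$subject_id, x$target, x$stride_frequency))
  print(as.data.frame(x)[, c("factor", "relative_phase_deg", "gain")],
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.coordination_sweep <- function(x, ...) {
  data.frame(subject_id = x$subject_id, target = x$target, factor = x$factors,
             relative_phase_deg = x$phase_by_factor, gain = x$gain_by_factor)
}

#' Export sweep results as a long-format CSV
#'
#' @param sweeps List of `coordination_sweep` objects.
#' @param path Output CSV path.
#' @return The table written, invisibly.
#' @export
write_sweeps <- function(sweeps, path) {
  df <- do.call(rbind, lapply(sweeps, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
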