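#' Trunk model parameters
#'
#' The forward model treats the thorax as a single rigid body with one
#' rotational degree of freedom about the longitudinal axis through L5S1,
#' coupled to the (prescribed) pelvis rotation by a linear torsion
#' spring-damper and driven by the arm-swing moment:
#'
#' \deqn{I \ddot\theta_T = M_{arm}(t) - k (\theta_T - \theta_P(t))
#'       - b (\dot\theta_T - \dot\theta_P(t))}
#'
#' @param stiffness Apparent axial trunk stiffness k, Nm/rad (>= 0).
#' @param damping Apparent axial trunk damping b, Nms/rad (>= 0).
#' @param inertia Thorax inertia I about the longitudinal axis, kg m^2 (> 0).
#' @return An object of class `trunk_model_params`.
#' @export
trunk_model_params <- function(stiffness, damping, inertia) {
  if (!all(is.finite(c(stiffness, damping, inertia))))
    stop("all model parameters must be finite")
  if (stiffness < 0) stop("stiffness must be >= 0")
  if (damping < 0) stop("damping must be >= 0")
  if (inertia <= 0) stop("inertia must be > 0")
  structure(list(stiffness = stiffness, damping = damping, inertia = inertia),
            class = "trunk_model_params")
}

#' @export
print.trunk_model_params <- function(x, ...) {
  cat(sprintf("<trunk_model_params> k = %.4g Nm/rad, b = %.4g Nms/rad, I = %.4g kg m^2\n",
              x$stiffness, x$damping, x$inertia))
  invisible(x)
}

#' Simulate axial thorax rotation with the forward-dynamic trunk model
#'
#' Integrates the trunk equation of motion with a classic fixed-step
#' fourth-order Runge-Kutta scheme at step `1/sample_rate`; pelvis angle,
#' pelvis velocity and arm moment are linearly interpolated at half steps.
#' Pelvis velocity, unless supplied, is obtained by central differencing of
#' the (optionally low-pass filtered) pelvis angle.
#'
#' @param params A [trunk_model_params()].
#' @param pelvis_angle Pelvis rotation, radians.
#' @param arm_moment Arm-swing moment, Nm; same length as `pelvis_angle`.
#' @param sample_rate Hz.
#' @param init Initial state: numeric `c(thorax_angle, thorax_velocity)` in
#'   rad and rad/s. Defaults to the pelvis angle and velocity at t = 0, which
#'   minimizes the start-up transient for pelvis-driven motion.
#' @param pelvis_velocity Optional pelvis angular velocity, rad/s.
#' @param lowpass_cutoff Optional cutoff (Hz) used to filter the pelvis angle
#'   before differentiation; `NULL` (default) differentiates the raw series.
#' @return Thorax rotation series, radians, same length as the inputs.
#' @export
simulate_thorax <- function(params, pelvis_angle, arm_moment, sample_rate,
                            init = NULL, pelvis_velocity = NULL,
                            lowpass_cutoff = NULL) {
  stopifnot(inherits(params, "trunk_model_params"))
  n <- length(pelvis_angle)
  if (length(arm_moment) != n)
    stop("pelvis_angle and arm_moment must have the same length")
  if (!all(is.finite(pelvis_angle)) || !all(is.finite(arm_moment)))
    stop("model inputs must be finite")
  if (is.null(pelvis_velocity)) {
    p <- if (is.null(lowpass_cutoff)) pelvis_angle
         else lowpass_filter(pelvis_angle, sample_rate, lowpass_cutoff)
    pelvis_velocity <- differentiate(p, sample_rate)
  }
  if (length(pelvis_velocity) != n)
    stop("pelvis_velocity must match pelvis_angle in length")
  if (is.null(init)) init <- c(pelvis_angle[1], pelvis_velocity[1])
  if (length(init) != 2 || !all(is.finite(init)))
    stop("init must be two finite numbers (angle, velocity)")
  rk4_trunk(params$stiffness, params$damping, params$inertia,
            pelvis_angle, pelvis_velocity, arm_moment,
            1 / sample_rate, init[1], init[2])
}

#' Closed-form steady-state frequency response of the trunk model
#'
#' For sinusoidal forcing at angular frequency `omega`, the linear model's
#' steady-state thorax amplitude is
#' \deqn{\Theta_T = \frac{(k + i b \omega)\,\Theta_P + M_{arm}}
#'                       {k - I\omega^2 + i b \omega}.}
#' This is the analytic oracle for [simulate_thorax()]: after transients
#' decay, the simulated response to `Im(Theta_P e^{i omega t})` pelvis motion
#' and `Im(M e^{i omega t})` arm moment equals `Im(Theta_T e^{i omega t})`.
#'
#' @param params A [trunk_model_params()].
#' @param omega Angular frequency, rad/s.
#' @param pelvis_amp Complex pelvis amplitude, rad.
#' @param arm_amp Complex arm-moment amplitude, Nm (default 0).
#' @return Complex thorax amplitude, rad. `Mod()` is the response amplitude;
#'   `Arg(theta_T) - Arg(theta_P)` the phase lead of thorax over pelvis.
#' @export
steady_state_response <- function(params, omega, pelvis_amp, arm_amp = 0 + 0i) {
  stopifnot(inherits(params, "trunk_model_params"))
  den <- complex(real = params$stiffness - params$inertia * omega^2,
                 imaginary = params$damping * omega)
  if (Mod(den) < 1e-12)
    stop("undamped resonance: k - I*omega^2 and b*omega both vanish; the steady-state response is unbounded")
  (complex(real = params$stiffness, imaginary = params$damping * omega) *
     pelvis_amp + arm_amp) / den
}

#' Estimate thorax axial inertia from anthropometrics
#'
#' Uses a homogeneous-cylinder model of the thorax: the segment mass is a
#' fixed fraction of body mass and the axial moment of inertia is
#' \eqn{I = \tfrac12 m_{thorax} r^2} with radius `circumference / (2 pi)`.
#' A direct `thorax_inertia` override in the anthropometrics wins. The
#' default mass fraction of 0.216 is the thorax share of body mass from
#' standard anthropometric tables. `thorax_length` is not used by this model.
#'
#' @param anthro A [subject_anthropometrics()].
#' @param mass_fraction Thorax share of body mass (dimensionless).
#' @return Inertia, kg m^2.
#' @export
estimate_thorax_inertia <- function(anthro, mass_fraction = 0.216) {
  stopifnot(inherits(anthro, "subject_anthropometrics"))
  if (!is.null(anthro$thorax_inertia)) return(anthro$thorax_inertia)
  if (is.null(anthro$mass) || is.null(anthro$thorax_circumference))
    stop("need either a thorax_inertia override or mass plus thorax_circumference")
  r <- anthro$thorax_circumference / (2 * pi)
  0.5 * (mass_fraction * anthro$mass) * r^2
}

#' Torsion spring-damper trunk moment
#'
#' The internal trunk moment exerted on the thorax by the passive
#' spring-damper: `-k * angle - b * velocity`, where `angle` is the
#' thorax-pelvis relative angle (rad) and `velocity` its rate (rad/s). The
#' sign is restoring: a positive relative angle produces a negative moment.
#'
#' @param params A [trunk_model_params()].
#' @param trunk_angle Thorax minus pelvis angle, rad.
#' @param trunk_velocity Relative angular velocity, rad/s.
#' @return Moment series, Nm.
#' @export
spring_damper_moment <- function(params, trunk_angle, trunk_velocity) {
  stopifnot(inherits(params, "trunk_model_params"))
  if (length(trunk_angle) != length(trunk_velocity))
    stop("trunk_angle and trunk_velocity must have the same length")
  -params$stiffness * trunk_angle - params$damping * trunk_velocity
}
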