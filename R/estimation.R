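# Nelder-Mead simplex in the fminsearch style: reflection 1, expansion 2,
# contraction 0.5, shrink 0.5; MATLAB-style initial simplex (5% perturbation
# per coordinate, 0.00025 for zero coordinates); termination when BOTH the
# objective spread and the parameter spread over the simplex fall below
# absolute tolerances.
nelder_mead <- function(fn, x0, tol_f = 1e-4, tol_x = 1e-4, max_iter = 2000) {
  n <- length(x0)
  V <- matrix(rep(x0, n + 1L), nrow = n)
  for (j in seq_len(n))
    V[j, j + 1L] <- if (x0[j] != 0) 1.05 * x0[j] else 0.00025
  fv <- apply(V, 2, fn)
  n_eval <- n + 1L
  rho <- 1; chi <- 2; psi <- 0.5; sigma <- 0.5
  iter <- 0L; converged <- FALSE
  repeat {
    ord <- order(fv)
    V <- V[, ord, drop = FALSE]; fv <- fv[ord]
    if (max(abs(fv[-1L] - fv[1L])) <= tol_f &&
        max(abs(V[, -1L, drop = FALSE] - V[, 1L])) <= tol_x) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    xbar <- rowMeans(V[, seq_len(n), drop = FALSE])
    xw <- V[, n + 1L]
    xr <- (1 + rho) * xbar - rho * xw
    fr <- fn(xr); n_eval <- n_eval + 1L
    if (fr < fv[1L]) {
      xe <- (1 + rho * chi) * xbar - rho * chi * xw
      fe <- fn(xe); n_eval <- n_eval + 1L
      if (fe < fr) { V[, n + 1L] <- xe; fv[n + 1L] <- fe }
      else         { V[, n + 1L] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      V[, n + 1L] <- xr; fv[n + 1L] <- fr
    } else {
      shrink <- FALSE
      if (fr < fv[n + 1L]) {  # outside contraction
        xc <- (1 + psi * rho) * xbar - psi * rho * xw
        fc <- fn(xc); n_eval <- n_eval + 1L
        if (fc <= fr) { V[, n + 1L] <- xc; fv[n + 1L] <- fc } else shrink <- TRUE
      } else {                # inside contraction
        xcc <- (1 - psi) * xbar + psi * xw
        fcc <- fn(xcc); n_eval <- n_eval + 1L
        if (fcc < fv[n + 1L]) { V[, n + 1L] <- xcc; fv[n + 1L] <- fcc } else shrink <- TRUE
      }
      if (shrink) {
        for (j in 2:(n + 1L)) {
          V[, j] <- V[, 1L] + sigma * (V[, j] - V[, 1L])
          fv[j] <- fn(V[, j]); n_eval <- n_eval + 1L
        }
      }
    }
  }
  ord <- order(fv)
  list(par = V[, ord[1L]], value = fv[ord[1L]], iterations = iter,
       converged = converged, n_eval = n_eval)
}

#' Identify apparent axial trunk stiffness and damping
#'
#' Fits the two free parameters of the forward-dynamic trunk model (stiffness
#' k, damping b) to one subject's recording by minimizing the root mean
#' squared error between observed and model-predicted axial thorax rotations,
#' using a Nelder-Mead simplex started at (100 Nm/rad, 1 Nms/rad) with
#' termination tolerance 1e-4 on both the objective (RMSE, degrees) and the
#' parameters. Samples within `burn_in` seconds of the start are excluded
#' from the objective to discount the integrator's initial transient
#' (`burn_in = 0` gives a strict whole-series objective). The search is
#' unconstrained; results with negative stiffness or damping are returned but
#' flagged `nonphysical`.
#'
#' @param rec A [trajectory_recording()] with pelvis, thorax and arm-moment
#'   series.
#' @param inertia Thorax axial inertia, kg m^2.
#' @param init Initial guess `c(stiffness, damping)`.
#' @param tol Absolute termination tolerance applied to both the objective
#'   and the parameters.
#' @param burn_in Seconds excluded from the start of the objective window.
#' @param lowpass_cutoff Zero-phase low-pass cutoff (Hz) applied to the
#'   angle series before differentiation; `NULL` disables filtering.
#' @param max_iter Maximum simplex iterations.
#' @return An object of class `trunk_fit` with elements `stiffness`,
#'   `damping`, `rmse` (deg), `common_variance` (%), `predicted_thorax`
#'   (deg, full length), `iterations`, `converged`, `initial_guess`,
#'   `tolerance`, `burn_in`, `nonphysical`, `inertia`, `subject_id`, `group`.
#' @export
fit_stiffness_damping <- function(rec, inertia, init = c(100, 1), tol = 1e-4,
                                  burn_in = 2, lowpass_cutoff = 10,
                                  max_iter = 2000) {
  validate_recording(rec)
  if (is.null(rec$thorax_angle))
    stop("recording has no thorax_angle series; cannot fit")
  if (is.null(rec$arm_moment))
    stop("recording has no arm_moment series; cannot fit")
  if (!is.finite(inertia) || inertia <= 0) stop("inertia must be > 0")

  fs <- rec$sample_rate
  deg2rad <- pi / 180
  pelvis_raw <- rec$pelvis_angle * deg2rad
  thorax_obs <- rec$thorax_angle            # degrees, objective scale
  pelvis <- if (is.null(lowpass_cutoff)) pelvis_raw
            else lowpass_filter(pelvis_raw, fs, lowpass_cutoff)
  pelvis_vel <- differentiate(pelvis, fs)
  thorax_rad <- thorax_obs * deg2rad
  thorax_smooth <- if (is.null(lowpass_cutoff)) thorax_rad
                   else lowpass_filter(thorax_rad, fs, lowpass_cutoff)
  init_state <- c(thorax_rad[1], differentiate(thorax_smooth, fs)[1])

  keep <- rec$time >= rec$time[1] + burn_in
  if (!any(keep)) stop("burn_in leaves no samples in the objective window")

  simulate_deg <- function(k, b) {
    rk4_trunk(k, b, inertia, pelvis, pelvis_vel, rec$arm_moment,
              1 / fs, init_state[1], init_state[2]) / deg2rad
  }
  objective <- function(x) {
    pred <- simulate_deg(x[1], x[2])
    sqrt(mean((thorax_obs[keep] - pred[keep])^2))
  }

  opt <- nelder_mead(objective, init, tol_f = tol, tol_x = tol,
                     max_iter = max_iter)
  pred <- simulate_deg(opt$par[1], opt$par[2])
  structure(list(
    stiffness = opt$par[1],
    damping = opt$par[2],
    rmse = opt$value,
    common_variance = goodness_of_fit(thorax_obs[keep], pred[keep]),
    predicted_thorax = pred,
    iterations = opt$iterations,
    converged = opt$converged,
    initial_guess = init,
    tolerance = tol,
    burn_in = burn_in,
    nonphysical = opt$par[1] < 0 || opt$par[2] < 0,
    inertia = inertia,
    n_eval = opt$n_eval,
    subject_id = rec$subject_id,
    group = rec$group
  ), class = "trunk_fit")
}

#' @export
print.trunk_fit <- function(x, ...) {
  cat(sprintf("<trunk_fit> subject %s\n", x$subject_id))
  cat(sprintf("  k = %.2f Nm/rad, b = %.3f Nms/rad (I = %.3f kg m^2)\n",
              x$stiffness, x$damping, x$inertia))
  cat(sprintf("  RMSE %.4f deg, common variance %.1f%%, %d iterations%s%s\n",
              x$rmse, x$common_variance, x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$nonphysical) " [NONPHYSICAL]" else ""))
  invisible(x)
}

#' Goodness of fit as percent common variance
#'
#' Common variance of two series, defined as 100 times the squared Pearson
#' correlation. Being correlation-based it is invariant to scale and offset,
#' and symmetric in its arguments.
#'
#' @param observed,predicted Equal-length numeric series (length >= 3) with
#'   nonzero variance.
#' @return Percent common variance in \[0, 100\].
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same length")
  if (length(observed) < 3) stop("need at least 3 samples")
  if (var(observed) == 0 || var(predicted) == 0)
    stop("zero-variance input: common variance is undefined")
  100 * cor(observed, predicted)^2
}

#' Normalize a moment, stiffness or damping to body size
#'
#' Dimensionless body-size normalization: moments and stiffnesses are divided
#' by `mass * g * height`; damping by `mass * g * height * sqrt(height / g)`
#' (the extra factor removes the time dimension using the pendular time scale
#' `sqrt(height / g)`).
#'
#' @param value Value in Nm, Nm/rad or Nms/rad.
#' @param kind One of `"moment"`, `"stiffness"`, `"damping"`.
#' @param anthro A [subject_anthropometrics()] with height and mass.
#' @param g Gravitational acceleration, m/s^2.
#' @return Dimensionless normalized value (linear in `value`).
#' @export
hof_normalize <- function(value, kind = c("moment", "stiffness", "damping"),
                          anthro, g = 9.81) {
  kind <- match.arg(kind)
  stopifnot(inherits(anthro, "subject_anthropometrics"))
  if (is.null(anthro$mass) || is.null(anthro$height))
    stop("anthropometrics must provide mass and height")
  base <- anthro$mass * g * anthro$height
  switch(kind,
         moment = value / base,
         stiffness = value / base,
         damping = value / (base * sqrt(anthro$height / g)))
}

#' Export fit results as a per-subject CSV
#'
#' @param fits List of `trunk_fit` objects.
#' @param path Output CSV path.
#' @return The table written, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  df <- do.call(rbind, lapply(fits, function(f) data.frame(
    subject_id = f$subject_id, group = f$group,
    stiffness_Nm_per_rad = f$stiffness, damping_Nms_per_rad = f$damping,
    rmse_deg = f$rmse, common_variance_pct = f$common_variance,
    converged = f$converged)))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
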