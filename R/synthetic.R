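#' Configuration for one synthetic gait subject
#'
#' Emulates a two-minute treadmill walk sampled at 100 Hz: near-sinusoidal
#' axial pelvis rotation at a stride frequency near 1 Hz (a fundamental plus
#' optional small higher harmonics), an arm-swing moment dominated by the
#' stride frequency, thorax rotation produced by the forward-dynamic model
#' with known ground-truth stiffness and damping, and additive white Gaussian
#' measurement noise on the angle channels.
#'
#' The default arm-moment timing (`arm_phase_lead = -pi/2`, i.e. the arm
#' moment lags pelvis rotation by a quarter cycle) places the subject in the
#' physiological regime where thorax rotations lag the pelvis and stiffness
#' and arm-swing moment push coordination in opposite directions; see the
#' methods vignette for the closed-form analysis behind this choice.
#'
#' @param stride_frequency Hz, in (0.5, 1.5).
#' @param pelvis_harmonics List of `c(harmonic, amplitude_deg, phase_rad)`
#'   triplets describing the pelvis rotation.
#' @param arm_amplitude Arm-swing moment amplitude, Nm.
#' @param arm_phase_lead Phase of the arm moment relative to the pelvis
#'   fundamental, rad (negative = the moment lags pelvis rotation).
#' @param truth_stiffness,truth_damping Ground-truth model parameters.
#' @param inertia Thorax axial inertia, kg m^2.
#' @param noise_sd Measurement noise SD on pelvis and thorax angles, degrees.
#' @param duration Seconds.
#' @param sample_rate Hz.
#' @param seed Integer seed for the noise realization.
#' @return An object of class `synthetic_subject_config`.
#' @export
synthetic_subject_config <- function(stride_frequency = 0.9,
                                     pelvis_harmonics = list(c(1, 4, 0)),
                                     arm_amplitude = 8,
                                     arm_phase_lead = -pi / 2,
                                     truth_stiffness = 124,
                                     truth_damping = 5,
                                     inertia = 0.2,
                                     noise_sd = 0.2,
                                     duration = 120,
                                     sample_rate = 100,
                                     seed = 1L) {
  if (stride_frequency <= 0.5 || stride_frequency >= 1.5)
    stop("stride_frequency must lie in (0.5, 1.5) Hz")
  n <- duration * sample_rate
  if (abs(n - round(n)) > 1e-9 || n < 2)
    stop("duration * sample_rate must be an integer >= 2")
  for (h in pelvis_harmonics) {
    if (length(h) != 3 || h[1] < 1 || h[2] < 0)
      stop("each pelvis harmonic must be c(harmonic >= 1, amplitude >= 0, phase)")
  }
  if (arm_amplitude < 0) stop("arm_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(stride_frequency = stride_frequency,
                 pelvis_harmonics = pelvis_harmonics,
                 arm_amplitude = arm_amplitude,
                 arm_phase_lead = arm_phase_lead,
                 truth_stiffness = truth_stiffness,
                 truth_damping = truth_damping,
                 inertia = inertia, noise_sd = noise_sd,
                 duration = duration, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "synthetic_subject_config")
}

synthetic_time <- function(cfg) {
  n <- round(cfg$duration * cfg$sample_rate)
  (seq_len(n) - 1) / cfg$sample_rate
}

#' Generate the noise-free pelvis rotation of a synthetic subject
#'
#' Sum of the configured harmonics of the stride frequency; measurement
#' noise is added later, when the full recording is assembled.
#'
#' @param cfg A [synthetic_subject_config()].
#' @return Pelvis rotation series, degrees.
#' @export
generate_pelvis <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_subject_config"))
  t <- synthetic_time(cfg)
  out <- numeric(length(t))
  for (h in cfg$pelvis_harmonics)
    out <- out + h[2] * sin(2 * pi * h[1] * cfg$stride_frequency * t + h[3])
  out
}

#' Generate the noise-free arm-swing moment of a synthetic subject
#'
#' A single stride-frequency sinusoid with amplitude `arm_amplitude` and
#' phase equal to the pelvis fundamental phase plus `arm_phase_lead`.
#'
#' @param cfg A [synthetic_subject_config()].
#' @return Arm-swing moment series, Nm.
#' @export
generate_arm_moment <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_subject_config"))
  t <- synthetic_time(cfg)
  ph1 <- pelvis_fundamental_phase(cfg)
  cfg$arm_amplitude *
    sin(2 * pi * cfg$stride_frequency * t + ph1 + cfg$arm_phase_lead)
}

pelvis_fundamental_phase <- function(cfg) {
  for (h in cfg$pelvis_harmonics) if (h[1] == 1) return(h[3])
  0
}

#' Generate one synthetic subject with known ground truth
#'
#' Closes the loop through [simulate_thorax()]: the thorax series is the
#' forward model's response to the generated pelvis rotation and arm-swing
#' moment under the ground-truth parameters, started from the analytic
#' steady state (so the recording is model-consistent from the first
#' sample), after which independent Gaussian measurement noise is added to
#' the pelvis and thorax angle channels.
#'
#' @param cfg A [synthetic_subject_config()].
#' @param subject_id,group Labels for the recording.
#' @return A list with `recording` (a [trajectory_recording()]), `truth`
#'   (a [trunk_model_params()]) and `config`.
#' @export
generate_subject <- function(cfg, subject_id = "synthetic", group = NA_character_) {
  stopifnot(inherits(cfg, "synthetic_subject_config"))
  truth <- trunk_model_params(cfg$truth_stiffness, cfg$truth_damping, cfg$inertia)
  t <- synthetic_time(cfg)
  deg2rad <- pi / 180
  pelvis_deg <- generate_pelvis(cfg)
  arm <- generate_arm_moment(cfg)

  # analytic steady-state initial conditions: signals are Im(A e^{i w t})
  ph1 <- pelvis_fundamental_phase(cfg)
  th0 <- 0i; om0 <- 0i
  for (h in cfg$pelvis_harmonics) {
    w <- 2 * pi * h[1] * cfg$stride_frequency
    p_amp <- h[2] * deg2rad * exp(1i * h[3])
    m_amp <- if (h[1] == 1)
      cfg$arm_amplitude * exp(1i * (ph1 + cfg$arm_phase_lead)) else 0 + 0i
    th <- steady_state_response(truth, w, p_amp, m_amp)
    th0 <- th0 + th
    om0 <- om0 + 1i * w * th
  }
  init <- c(Im(th0), Im(om0))

  thorax_rad <- simulate_thorax(truth, pelvis_deg * deg2rad, arm,
                                cfg$sample_rate, init = init)
  thorax_deg <- thorax_rad / deg2rad

  set.seed(cfg$seed)
  n <- length(t)
  pelvis_noisy <- pelvis_deg + rnorm(n, 0, cfg$noise_sd)
  thorax_noisy <- thorax_deg + rnorm(n, 0, cfg$noise_sd)

  rec <- trajectory_recording(time = t, pelvis_angle = pelvis_noisy,
                              thorax_angle = thorax_noisy, arm_moment = arm,
                              sample_rate = cfg$sample_rate,
                              subject_id = subject_id, group = group)
  list(recording = rec, truth = truth, config = cfg)
}

#' Configuration for a synthetic two-group cohort
#'
#' Population distributions emulate the study cohort the analysis assumes:
#' two groups of 15, stature about 1.85 (SD 0.10) m, body mass about
#' 82 (SD 12) kg, apparent axial trunk stiffness 124 (SD 54) Nm/rad
#' truncated above 10, damping 5 (SD 2) Nms/rad truncated above 0.1, with
#' jitter on arm-swing amplitude, arm-moment timing and stride frequency.
#'
#' @param n_per_group Subjects per group.
#' @param groups Two group labels.
#' @param height_mean,height_sd Stature distribution, m.
#' @param mass_mean,mass_sd Body-mass distribution, kg.
#' @param circumference_mean,circumference_sd Thorax circumference, m.
#' @param stiffness_mean,stiffness_sd,stiffness_min Ground-truth stiffness
#'   distribution (truncated normal), Nm/rad.
#' @param damping_mean,damping_sd,damping_min Ground-truth damping
#'   distribution (truncated normal), Nms/rad.
#' @param arm_amplitude_mean,arm_amplitude_sd,arm_amplitude_min Arm-moment
#'   amplitude distribution, Nm.
#' @param arm_phase_mean,arm_phase_sd Arm-moment phase relative to the
#'   pelvis fundamental, rad.
#' @param stride_frequency_mean,stride_frequency_sd Stride frequency, Hz
#'   (truncated to (0.55, 1.45)).
#' @param duration,sample_rate,noise_sd Per-subject recording settings.
#' @param seed Master seed; per-subject seeds are derived as `seed + index`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 15,
                          groups = c("control", "low_back_pain"),
                          height_mean = 1.85, height_sd = 0.10,
                          mass_mean = 82, mass_sd = 12,
                          circumference_mean = 0.95, circumference_sd = 0.05,
                          stiffness_mean = 124, stiffness_sd = 54,
                          stiffness_min = 10,
                          damping_mean = 5, damping_sd = 2, damping_min = 0.1,
                          arm_amplitude_mean = 8, arm_amplitude_sd = 1.5,
                          arm_amplitude_min = 1,
                          arm_phase_mean = -pi / 2, arm_phase_sd = 0.07,
                          stride_frequency_mean = 0.9,
                          stride_frequency_sd = 0.05,
                          duration = 120, sample_rate = 100, noise_sd = 0.2,
                          seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (length(groups) != 2) stop("exactly two group labels are required")
  if (any(c(height_sd, mass_sd, circumference_sd, stiffness_sd, damping_sd,
            arm_amplitude_sd, arm_phase_sd, stride_frequency_sd) < 0))
    stop("all SDs must be >= 0")
  structure(as.list(environment()), class = "cohort_config")
}

# truncated-normal sampling by rejection
rtruncnorm_ <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Draw per-subject cohort parameters
#'
#' Draws anthropometrics and ground-truth model parameters for every subject
#' from the configured truncated normals, without synthesizing recordings.
#' Deterministic given the master seed.
#'
#' @param cfg A [cohort_config()].
#' @return Data frame with one row per subject: labels, anthropometrics,
#'   ground truth and the derived per-subject simulation seed.
#' @export
draw_cohort_params <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- 2L * cfg$n_per_group
  set.seed(cfg$seed)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(cfg$groups, each = cfg$n_per_group),
    height = rtruncnorm_(n, cfg$height_mean, cfg$height_sd, 1.4, 2.3),
    mass = rtruncnorm_(n, cfg$mass_mean, cfg$mass_sd, 40, 160),
    thorax_circumference = rtruncnorm_(n, cfg$circumference_mean,
                                       cfg$circumference_sd, 0.6, 1.4),
    truth_stiffness = rtruncnorm_(n, cfg$stiffness_mean, cfg$stiffness_sd,
                                  cfg$stiffness_min, Inf),
    truth_damping = rtruncnorm_(n, cfg$damping_mean, cfg$damping_sd,
                                cfg$damping_min, Inf),
    arm_amplitude = rtruncnorm_(n, cfg$arm_amplitude_mean,
                                cfg$arm_amplitude_sd, cfg$arm_amplitude_min, Inf),
    arm_phase_lead = rtruncnorm_(n, cfg$arm_phase_mean, cfg$arm_phase_sd,
                                 -pi, 0),
    stride_frequency = rtruncnorm_(n, cfg$stride_frequency_mean,
                                   cfg$stride_frequency_sd, 0.55, 1.45),
    seed = cfg$seed + seq_len(n))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameters with [draw_cohort_params()], derives each
#' thorax inertia from the drawn anthropometrics via
#' [estimate_thorax_inertia()], and synthesizes every subject's recording
#' with [generate_subject()]. Byte-identical on re-run with the same config.
#'
#' @param cfg A [cohort_config()].
#' @return A list of subjects, each a list with `recording`, `anthro`,
#'   `truth` and `config`.
#' @export
generate_cohort <- function(cfg) {
  pars <- draw_cohort_params(cfg)
  lapply(seq_len(nrow(pars)), function(i) {
    p <- pars[i, ]
    anthro <- subject_anthropometrics(height = p$height, mass = p$mass,
                                      thorax_circumference = p$thorax_circumference,
                                      group = p$group)
    inertia <- estimate_thorax_inertia(anthro)
    scfg <- synthetic_subject_config(
      stride_frequency = p$stride_frequency,
      arm_amplitude = p$arm_amplitude,
      arm_phase_lead = p$arm_phase_lead,
      truth_stiffness = p$truth_stiffness,
      truth_damping = p$truth_damping,
      inertia = inertia,
      noise_sd = cfg$noise_sd, duration = cfg$duration,
      sample_rate = cfg$sample_rate, seed = p$seed)
    subj <- generate_subject(scfg, subject_id = p$subject_id, group = p$group)
    subj$anthro <- anthro
    subj
  })
}

#' Write a cohort to a directory
#'
#' One recording CSV per subject, one `anthropometrics.json`, and one
#' `ground_truth.csv` with the generating parameters.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anthro <- list()
  truth <- list()
  for (s in cohort) {
    id <- s$recording$subject_id
    write_recording(s$recording, file.path(dir, paste0(id, ".csv")))
    anthro[[id]] <- list(height_m = s$anthro$height, mass_kg = s$anthro$mass,
                         thorax_circumference_m = s$anthro$thorax_circumference,
                         group = s$anthro$group)
    truth[[id]] <- data.frame(subject_id = id, group = s$recording$group,
                              stiffness_Nm_per_rad = s$truth$stiffness,
                              damping_Nms_per_rad = s$truth$damping,
                              inertia_kgm2 = s$truth$inertia)
  }
  jsonlite::write_json(anthro, file.path(dir, "anthropometrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(do.call(rbind, truth), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list of subjects, each with `recording`, `anthro`, and `truth`
#'   (`NULL` when no `ground_truth.csv` is present).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  aj <- file.path(dir, "anthropometrics.json")
  anthro <- if (file.exists(aj)) jsonlite::read_json(aj, simplifyVector = FALSE)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) read.csv(gt_path)
  files <- sort(setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                        gt_path))
  if (length(files) == 0) stop("no recording CSVs in ", dir)
  lapply(files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    a <- anthro[[id]]
    group <- if (!is.null(a$group)) a$group else NA_character_
    rec <- read_recording(f, subject_id = id, group = group)
    subj <- list(recording = rec, anthro = NULL, truth = NULL)
    if (!is.null(a))
      subj$anthro <- subject_anthropometrics(
        height = a$height_m, mass = a$mass_kg,
        thorax_circumference = a$thorax_circumference_m,
        thorax_inertia = a$thorax_inertia_kgm2, group = group)
    if (!is.null(gt) && id %in% gt$subject_id) {
      r <- gt[gt$subject_id == id, ]
      subj$truth <- trunk_model_params(r$stiffness_Nm_per_rad,
                                       r$damping_Nms_per_rad, r$inertia_kgm2)
    }
    subj
  })
}
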