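#' Pipeline configuration
#'
#' Exactly one input source must be given: a cohort directory (written by
#' [write_cohort()] or following the same layout) or a [cohort_config()] to
#' synthesize a cohort in memory.
#'
#' @param output_dir Directory for all output tables and the run log.
#' @param cohort_dir Cohort directory, or `NULL`.
#' @param cohort A [cohort_config()], or `NULL`.
#' @param lowpass_cutoff Preprocessing low-pass cutoff, Hz (`NULL` disables).
#' @param burn_in Objective burn-in for fitting, s.
#' @param fit_init,fit_tol Initial guess and tolerance for the fit.
#' @param sweep_factors Multiplication factors for the stiffness and
#'   arm-moment sweeps.
#' @param sweep_transient Seconds discarded before sweep metrics.
#' @param seed Seed for any synthetic generation.
#' @param verbose Log progress to stderr.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, cohort_dir = NULL, cohort = NULL,
                            lowpass_cutoff = 10, burn_in = 2,
                            fit_init = c(100, 1), fit_tol = 1e-4,
                            sweep_factors = c(0.5, 0.75, 1, 1.25, 1.5),
                            sweep_transient = 10, seed = 1L, verbose = TRUE) {
  if (is.null(cohort_dir) == is.null(cohort))
    stop("exactly one input source (cohort_dir or cohort config) is required")
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop("cohort directory not found: ", cohort_dir)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

log_msg <- function(verbose, ..., log_lines) {
  msg <- paste0(...)
  if (verbose) message(msg)
  c(log_lines, msg)
}

#' Run the full analysis pipeline
#'
#' Chains cohort loading or generation, per-subject stiffness/damping
#' fitting, coordination metrics, stiffness and arm-moment sweeps, the
#' inverse-dynamics stiffness route with the two-method comparison,
#' group-difference checks with pooling, and the coordination-to-stiffness
#' regression. Writes, into `output_dir`: `fits.csv`, `coordination.csv`,
#' `sweeps.csv`, `estimator_comparison.csv`, `estimator_comparison.json`,
#' `regression.json`, `group_tests.csv` and `run.log`. A subject whose
#' processing fails is logged, skipped and counted; the pipeline continues.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the per-subject table, the comparison, the
#'   regression, the group report and the number of skipped subjects.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  lg <- character()
  lg <- log_msg(cfg$verbose, "trunkcoord ", as.character(packageVersion("trunkcoord")),
                " | R ", R.version.string, log_lines = lg)
  lg <- log_msg(cfg$verbose, "seed: ", cfg$seed, log_lines = lg)

  cohort <- if (!is.null(cfg$cohort_dir)) {
    lg <- log_msg(cfg$verbose, "input: cohort directory ", cfg$cohort_dir,
                  log_lines = lg)
    read_cohort(cfg$cohort_dir)
  } else {
    cc <- cfg$cohort
    cc$seed <- cfg$seed
    lg <- log_msg(cfg$verbose, "input: synthetic cohort, 2 x ", cc$n_per_group,
                  " subjects", log_lines = lg)
    generate_cohort(cc)
  }

  rows <- list(); fits <- list(); coords <- list(); sweeps <- list()
  skipped <- 0L
  for (s in cohort) {
    id <- s$recording$subject_id
    res <- tryCatch({
      inertia <- if (!is.null(s$truth)) s$truth$inertia
                 else estimate_thorax_inertia(s$anthro)
      fit <- fit_stiffness_damping(s$recording, inertia,
                                   init = cfg$fit_init, tol = cfg$fit_tol,
                                   burn_in = cfg$burn_in,
                                   lowpass_cutoff = cfg$lowpass_cutoff)
      coord <- coordination_metrics(s$recording)
      params <- trunk_model_params(fit$stiffness, max(fit$damping, 0), inertia)
      sw_k <- sweep_coordination(s$recording, params, "stiffness",
                                 cfg$sweep_factors, cfg$sweep_transient)
      sw_m <- sweep_coordination(s$recording, params, "arm_moment",
                                 cfg$sweep_factors, cfg$sweep_transient)
      inv <- stiffness_from_regression(
        trunk_moment_from_kinematics(s$recording, inertia, cfg$lowpass_cutoff),
        (s$recording$thorax_angle - s$recording$pelvis_angle) * pi / 180)
      norm_k <- if (!is.null(s$anthro)) hof_normalize(fit$stiffness, "stiffness", s$anthro) else NA
      norm_b <- if (!is.null(s$anthro)) hof_normalize(fit$damping, "damping", s$anthro) else NA
      arm_rms <- sqrt(mean(s$recording$arm_moment^2))
      norm_arm <- if (!is.null(s$anthro)) hof_normalize(arm_rms, "moment", s$anthro) else NA
      list(fit = fit, coord = coord, sweeps = list(sw_k, sw_m),
           row = data.frame(
             subject_id = id, group = s$recording$group,
             stiffness_Nm_per_rad = fit$stiffness,
             damping_Nms_per_rad = fit$damping,
             inverse_stiffness_Nm_per_rad = inv$slope,
             rmse_deg = fit$rmse, common_variance_pct = fit$common_variance,
             converged = fit$converged,
             stride_frequency_hz = coord$stride_frequency,
             relative_phase_deg = coord$relative_phase, gain = coord$gain,
             arm_moment_rms_Nm = arm_rms,
             stiffness_norm = norm_k, damping_norm = norm_b,
             arm_moment_norm = norm_arm,
             truth_stiffness = if (!is.null(s$truth)) s$truth$stiffness else NA))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
      lg <- log_msg(cfg$verbose, "SKIPPED subject ", id, ": ",
                    conditionMessage(res), log_lines = lg)
      next
    }
    rows[[id]] <- res$row; fits[[id]] <- res$fit; coords[[id]] <- res$coord
    sweeps <- c(sweeps, res$sweeps)
  }
  if (length(rows) == 0) stop("all subjects failed; no outputs written")
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL

  write_fit_results(fits, file.path(cfg$output_dir, "fits.csv"))
  write_coordination(coords, file.path(cfg$output_dir, "coordination.csv"))
  write_sweeps(sweeps, file.path(cfg$output_dir, "sweeps.csv"))

  cmp <- compare_estimators(tbl$stiffness_Nm_per_rad,
                            tbl$inverse_stiffness_Nm_per_rad, tbl$subject_id)
  write_stiffness_comparison(cmp,
                             file.path(cfg$output_dir, "estimator_comparison.csv"),
                             file.path(cfg$output_dir, "estimator_comparison.json"))

  # group differences on the pooled-analysis outcomes, then pool
  outcome_cols <- c("stiffness_norm", "damping_norm", "arm_moment_norm",
                    "relative_phase_deg", "gain")
  have <- outcome_cols[colSums(!is.na(tbl[outcome_cols])) == nrow(tbl)]
  grp <- tryCatch(pool_groups(tbl[, c("group", have)]), error = function(e) e)
  if (inherits(grp, "error")) {
    lg <- log_msg(cfg$verbose, "group check skipped: ", conditionMessage(grp),
                  log_lines = lg)
    grp <- NULL
  } else {
    write.csv(grp$tests, file.path(cfg$output_dir, "group_tests.csv"),
              row.names = FALSE)
  }

  dep <- if (all(!is.na(tbl$stiffness_norm))) tbl$stiffness_norm
         else tbl$stiffness_Nm_per_rad
  reg <- tryCatch({
    r <- predict_stiffness(tbl$relative_phase_deg, tbl$gain, dep)
    ks <- lapply(list(stiffness = dep, phase = tbl$relative_phase_deg,
                      gain = tbl$gain), ks_normality)
    write_regression(r, file.path(cfg$output_dir, "regression.json"),
                     extra = list(ks_normality = ks))
    r
  }, error = function(e) {
    lg <<- log_msg(cfg$verbose, "regression skipped: ", conditionMessage(e),
                   log_lines = lg)
    NULL
  })

  lg <- log_msg(cfg$verbose, "subjects processed: ", nrow(tbl),
                ", skipped: ", skipped, log_lines = lg)
  cfg_echo <- cfg[c("lowpass_cutoff", "burn_in", "fit_init", "fit_tol",
                    "sweep_factors", "sweep_transient", "seed")]
  lg <- c(lg, paste0("config: ", jsonlite::toJSON(cfg_echo, auto_unbox = TRUE)))
  writeLines(lg, file.path(cfg$output_dir, "run.log"))

  invisible(list(table = tbl, comparison = cmp, regression = reg,
                 group_report = grp, skipped = skipped))
}
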