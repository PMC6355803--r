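test_that("generated pelvis rotation has the configured spectrum and range", {
  cfg <- synthetic_subject_config()
  pel <- generate_pelvis(cfg)
  expect_length(pel, 12000)
  ps <- power_spectrum(pel, cfg$sample_rate)
  expect_equal(ps$frequency[which.max(ps$power)], 0.9,
               tolerance = 100 / 12000 + 1e-9)
  expect_equal(max(pel) - min(pel), 8, tolerance = 0.01)  # peak-to-peak 2*4 deg
  zero <- synthetic_subject_config(pelvis_harmonics = list(c(1, 0, 0)),
                                   arm_amplitude = 0)
  expect_equal(generate_pelvis(zero), rep(0, 12000))
  expect_equal(generate_arm_moment(zero), rep(0, 12000))
  expect_identical(generate_pelvis(cfg), generate_pelvis(cfg))
})

test_that("the arm moment carries the configured amplitude and timing", {
  cfg <- synthetic_subject_config()
  arm <- generate_arm_moment(cfg)
  expect_equal(max(abs(arm)), 8, tolerance = 0.01)
  # default quarter-cycle lag: cross-correlation peaks a quarter period early
  quarter <- synthetic_subject_config(arm_phase_lead = -pi / 2)
  pel <- generate_pelvis(quarter)
  armq <- generate_arm_moment(quarter)
  period <- round(quarter$sample_rate / quarter$stride_frequency)
  cc <- ccf(armq, pel, lag.max = period, plot = FALSE)
  lag_at_peak <- cc$lag[which.max(cc$acf)]
  expect_equal(abs(lag_at_peak), round(period / 4), tolerance = 1)
})

test_that("generated subjects are model-consistent with recoverable truth", {
  cfg <- synthetic_subject_config(noise_sd = 0)
  s <- generate_subject(cfg)
  expect_s3_class(s$recording, "trajectory_recording")
  expect_length(s$recording$time, 12000)
  fit <- fit_stiffness_damping(s$recording, cfg$inertia)
  expect_lt(abs(fit$stiffness - cfg$truth_stiffness) / cfg$truth_stiffness, 0.01)
  expect_lt(abs(fit$damping - cfg$truth_damping) / cfg$truth_damping, 0.05)
})

test_that("seeds control only the noise realization", {
  base <- lapply(c(1, 2), function(sd) generate_subject(
    synthetic_subject_config(duration = 10, seed = sd)))
  expect_false(identical(base[[1]]$recording$pelvis_angle,
                         base[[2]]$recording$pelvis_angle))
  # noise-free construction identical underneath
  clean <- lapply(c(1, 2), function(sd) generate_subject(
    synthetic_subject_config(duration = 10, seed = sd, noise_sd = 0)))
  expect_identical(clean[[1]]$recording$pelvis_angle,
                   clean[[2]]$recording$pelvis_angle)
  expect_identical(clean[[1]]$recording$thorax_angle,
                   clean[[2]]$recording$thorax_angle)
})

test_that("cohorts respect truncation bounds and are reproducible", {
  cfg <- cohort_config(n_per_group = 3, duration = 10)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 6)
  for (s in cohort) {
    expect_s3_class(s$recording, "trajectory_recording")
    expect_gt(s$anthro$height, 1.4); expect_lt(s$anthro$height, 2.3)
    expect_gt(s$truth$stiffness, 10)
    expect_gt(s$truth$damping, 0.1)
  }
  again <- generate_cohort(cfg)
  expect_identical(cohort[[4]]$recording$thorax_angle,
                   again[[4]]$recording$thorax_angle)
})

test_that("drawn stiffness means match the population within sampling error", {
  cfg <- cohort_config(n_per_group = 100)
  pars <- draw_cohort_params(cfg)
  expect_equal(nrow(pars), 200)
  se <- 54 / sqrt(200)
  expect_lt(abs(mean(pars$truth_stiffness) - 124), 3 * se)
})

test_that("stride-frequency detection returns the configured value for every subject", {
  cfg <- cohort_config(n_per_group = 4, duration = 30)
  cohort <- generate_cohort(cfg)
  pars <- draw_cohort_params(cfg)
  for (i in seq_along(cohort)) {
    f <- stride_frequency(cohort[[i]]$recording$pelvis_angle,
                          cohort[[i]]$recording$sample_rate)
    bin <- cohort[[i]]$recording$sample_rate /
      length(cohort[[i]]$recording$pelvis_angle)
    expect_lt(abs(f - pars$stride_frequency[i]), bin + 1e-9)
  }
})

test_that("cohorts round-trip through a directory", {
  cfg <- cohort_config(n_per_group = 2, duration = 5)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "anthropometrics.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- read_cohort(dir)
  expect_length(back, 4)
  i <- which(vapply(back, function(s) s$recording$subject_id, "") == "S01")
  orig <- cohort[[1]]
  expect_equal(back[[i]]$recording$thorax_angle, orig$recording$thorax_angle,
               tolerance = 1e-9)
  expect_equal(back[[i]]$truth$stiffness, orig$truth$stiffness)
  expect_equal(back[[i]]$anthro$mass, orig$anthro$mass)
})

test_that("end-to-end recovery over a seeded cohort is accurate and well fit", {
  cfg <- cohort_config(n_per_group = 10, duration = 60)
  cohort <- generate_cohort(cfg)
  err <- cv <- numeric(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    fit <- fit_stiffness_damping(s$recording, s$truth$inertia)
    err[i] <- abs(fit$stiffness - s$truth$stiffness) / s$truth$stiffness
    cv[i] <- fit$common_variance
  }
  expect_lt(median(err), 0.02)
  expect_true(all(cv > 95))
})
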