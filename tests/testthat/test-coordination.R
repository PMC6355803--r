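test_that("the periodogram localizes spectral peaks with Parseval-consistent power", {
  t <- (0:11999) / 100
  ps <- power_spectrum(sin(2 * pi * 0.9 * t), 100)
  expect_equal(ps$frequency[which.max(ps$power)], 0.9,
               tolerance = 100 / 12000 + 1e-9)
  expect_lt(max(power_spectrum(rep(5, 1000), 100)$power), 1e-12)
  two <- 4 * sin(2 * pi * 0.9 * t) + 1 * sin(2 * pi * 1.8 * t)
  ps2 <- power_spectrum(two, 100)
  i1 <- which.min(abs(ps2$frequency - 0.9))
  i2 <- which.min(abs(ps2$frequency - 1.8))
  expect_equal(ps2$power[i1] / ps2$power[i2], 16, tolerance = 0.01)
  expect_error(power_spectrum(1:8, 100), "too short")
})

test_that("stride frequency is the in-band peak closest to 1 Hz", {
  t <- (0:11999) / 100
  expect_equal(stride_frequency(4 * sin(2 * pi * 0.9 * t), 100), 0.9,
               tolerance = 100 / 12000 + 1e-9)
  # equal-power peaks at 0.7 and 1.2 Hz: proximity to 1 Hz decides
  two <- sin(2 * pi * 0.7 * t) + sin(2 * pi * 1.2 * t)
  expect_equal(stride_frequency(two, 100), 1.2, tolerance = 100 / 12000 + 1e-9)
  expect_error(stride_frequency(rep(1, 12000), 100), "no qualifying")
})

test_that("FRF identities hold exactly", {
  rec <- sine_recording(duration = 40)
  frf <- frf_at_frequency(rec$pelvis_angle, rec$pelvis_angle, 100, 0.9)
  expect_equal(frf$relative_phase, 0, tolerance = 1e-9)
  expect_equal(frf$gain, 1, tolerance = 1e-12)
  anti <- frf_at_frequency(rec$pelvis_angle, -rec$pelvis_angle, 100, 0.9)
  expect_equal(anti$relative_phase, 180)  # wrapped into (-180, 180]
  expect_equal(anti$gain, 1, tolerance = 1e-12)
})

test_that("a quarter-cycle lag at half amplitude gives (-90 deg, 0.5)", {
  t <- (0:11999) / 100
  frf <- frf_at_frequency(4 * sin(2 * pi * 0.9 * t),
                          2 * sin(2 * pi * 0.9 * t - pi / 2), 100, 0.9)
  expect_equal(frf$relative_phase, -90, tolerance = 0.1)
  expect_equal(frf$gain, 0.5, tolerance = 1e-3)
})

test_that("FRF is reciprocal, offset-invariant and wraps correctly", {
  t <- (0:5999) / 100
  pel <- 4 * sin(2 * pi * 0.9 * t) + 0.5 * sin(2 * pi * 1.8 * t + 1)
  tho <- 2.4 * sin(2 * pi * 0.9 * t - 1.1) + 0.2 * sin(2 * pi * 1.8 * t)
  a <- frf_at_frequency(pel, tho, 100, 0.9)
  b <- frf_at_frequency(tho, pel, 100, 0.9)
  expect_equal(a$gain * b$gain, 1, tolerance = 1e-6)
  expect_equal((a$relative_phase + b$relative_phase) %% 360, 0,
               tolerance = 1e-6)
  off <- frf_at_frequency(pel + 13, tho - 4, 100, 0.9)
  expect_equal(off$gain, a$gain, tolerance = 1e-9)
  # phases near the wrap stay inside (-180, 180]
  for (d in c(-181, -180.001, 179.999, 180, 181)) {
    fr <- frf_at_frequency(4 * sin(2 * pi * 0.9 * t),
                           4 * sin(2 * pi * 0.9 * t + d * pi / 180), 100, 0.9)
    expect_true(fr$relative_phase > -180 && fr$relative_phase <= 180)
  }
})

test_that("coordination metrics recover a known construction", {
  t <- (0:11999) / 100
  rec <- trajectory_recording(
    time = t,
    pelvis_angle = 4 * sin(2 * pi * 0.9 * t),
    thorax_angle = 0.8 * 4 * sin(2 * pi * 0.9 * t - 60 * pi / 180),
    sample_rate = 100)
  m <- coordination_metrics(rec)
  expect_equal(m$stride_frequency, 0.9, tolerance = 100 / 12000 + 1e-9)
  expect_equal(m$relative_phase, -60, tolerance = 0.1)
  expect_equal(m$gain, 0.8, tolerance = 1e-3)
  same <- trajectory_recording(time = t, pelvis_angle = rec$pelvis_angle,
                               thorax_angle = rec$pelvis_angle,
                               sample_rate = 100)
  ms <- coordination_metrics(same)
  expect_equal(ms$relative_phase, 0, tolerance = 1e-6)
  expect_equal(ms$gain, 1, tolerance = 1e-9)
  rec$thorax_angle <- NULL
  expect_error(coordination_metrics(rec), "thorax")
})

test_that("coordination metrics agree with the model's closed-form response", {
  cfg <- synthetic_subject_config(noise_sd = 0)
  s <- generate_subject(cfg)
  m <- coordination_metrics(s$recording)
  om <- 2 * pi * cfg$stride_frequency
  H <- steady_state_response(s$truth, om, 4 * pi / 180 + 0i,
                             8 * exp(1i * cfg$arm_phase_lead)) / (4 * pi / 180)
  expect_equal(m$relative_phase, Arg(H) * 180 / pi, tolerance = 0.5)
  expect_equal(m$gain, Mod(H), tolerance = 1e-2)
})

test_that("the circular mean respects the phase wrap", {
  expect_equal(circular_mean_deg(c(179, -179)), 180, tolerance = 1e-9)
  expect_equal(circular_mean_deg(c(-10, 10)), 0, tolerance = 1e-9)
})
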