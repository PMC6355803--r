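test_that("recordings round-trip through CSV within 1e-9", {
  rec <- sine_recording(duration = 5, thorax_phase = -1, arm_amp = 8,
                        subject_id = "rt", group = "control")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, subject_id = "rt", group = "control")
  expect_equal(back$time, rec$time, tolerance = 1e-9)
  expect_equal(back$pelvis_angle, rec$pelvis_angle, tolerance = 1e-9)
  expect_equal(back$thorax_angle, rec$thorax_angle, tolerance = 1e-9)
  expect_equal(back$arm_moment, rec$arm_moment, tolerance = 1e-9)
  expect_equal(back$sample_rate, rec$sample_rate, tolerance = 1e-9)
})

test_that("a recording without thorax writes and reads without that column", {
  rec <- trajectory_recording(time = (0:99) / 100, pelvis_angle = sin(1:100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_setequal(header, c("time_s", "pelvis_deg"))
  expect_null(read_recording(path)$thorax_angle)
})

test_that("invalid recordings are rejected with informative errors", {
  expect_error(trajectory_recording(time = c(0, 0.01, 0.03),
                                    pelvis_angle = c(1, 2, 3)),
               "non-uniform")
  expect_error(trajectory_recording(time = 0, pelvis_angle = 1), "at least 2")
  expect_error(trajectory_recording(time = c(0, 0.01), pelvis_angle = c(1, NA)),
               "pelvis_angle.*non-finite")
  expect_error(trajectory_recording(time = c(0, 0.01, 0.02),
                                    pelvis_angle = 1:2),
               "length")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:3), path, row.names = FALSE)
  expect_error(read_recording(path), "time_s")
})

test_that("a 12000-row file at 100 Hz has duration 119.99 s", {
  rec <- trajectory_recording(time = (0:11999) / 100,
                              pelvis_angle = sin((0:11999) / 100))
  expect_equal(rec$sample_rate, 100)
  expect_equal(rec$time[length(rec$time)] - rec$time[1], 119.99)
})

test_that("zero-phase low-pass preserves DC and passband, kills stopband", {
  expect_equal(lowpass_filter(rep(2.5, 400), 100, 10), rep(2.5, 400),
               tolerance = 1e-9)
  t <- (0:5999) / 100
  s1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_filter(s1, 100, 10)
  expect_lt(abs(max(abs(y1)) / max(abs(s1)) - 1), 0.01)   # amplitude within 1%
  cc <- ccf(y1, s1, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)              # zero phase lag
  y40 <- lowpass_filter(sin(2 * pi * 40 * t), 100, 10)
  expect_lt(max(abs(y40[500:5500])), 0.1)                 # > 90% attenuation
  expect_error(lowpass_filter(s1, 100, 50), "Nyquist")
  expect_error(lowpass_filter(s1[1:10], 100, 10), "too short")
})

test_that("low-pass is idempotent for signals below cutoff", {
  t <- (0:5999) / 100
  s <- sin(2 * pi * 0.9 * t) + 0.4 * sin(2 * pi * 1.8 * t)
  y1 <- lowpass_filter(s, 100, 10)
  y2 <- lowpass_filter(y1, 100, 10)
  expect_lt(max(abs(y2 - y1)) / max(abs(y1)), 0.001)
})

test_that("differentiation matches analytic derivatives", {
  expect_equal(differentiate(rep(4, 100), 100), rep(0, 100))
  ramp <- 2 * (0:99) / 100
  expect_equal(differentiate(ramp, 100)[2:99], rep(2, 98), tolerance = 1e-12)
  t <- (0:5999) / 100
  d <- differentiate(sin(2 * pi * 0.9 * t), 100)
  truth <- 2 * pi * 0.9 * cos(2 * pi * 0.9 * t)
  expect_lt(max(abs(d - truth)[10:5990]), 1e-2)
  expect_error(differentiate(c(1, 2), 100), "too short")
})

test_that("second-order differentiation equals two first-order passes", {
  t <- (0:999) / 100
  s <- sin(2 * pi * 0.9 * t) + 0.3 * cos(2 * pi * 1.8 * t)
  twice <- differentiate(differentiate(s, 100), 100)
  once <- differentiate(s, 100, order = 2)
  interior <- 5:995
  expect_equal(once[interior], twice[interior], tolerance = 1e-6)
})

test_that("anthropometrics validate and round-trip through JSON", {
  a <- subject_anthropometrics(1.86, 80, thorax_circumference = 0.95,
                               group = "control")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(height_m = 1.86, mass_kg = 80,
                            thorax_circumference_m = 0.95, group = "control"),
                       path, auto_unbox = TRUE)
  b <- read_anthropometrics(path)
  expect_equal(b$height, a$height)
  expect_equal(b$thorax_circumference, 0.95)
  expect_error(subject_anthropometrics(0.3, 80), "height")
  expect_error(subject_anthropometrics(1.8, 10), "mass")
})
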