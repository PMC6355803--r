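test_that("common variance matches a brute-force Pearson computation", {
  expect_equal(common_variance(1:10, 1:10)$common_variance, 100)
  t <- (0:999) / 100
  cv <- common_variance(sin(2 * pi * t), cos(2 * pi * t))
  expect_lt(cv$common_variance, 1e-6)
  set.seed(17)
  x <- rnorm(30); y <- rnorm(30)
  got <- common_variance(x, y)
  ora <- bf_pearson(x, y)
  expect_equal(got$common_variance, 100 * ora$r^2, tolerance = 1e-9)
  expect_equal(got$p_value, ora$p, tolerance = 1e-6)
  expect_equal(got$common_variance, common_variance(y, x)$common_variance)
  expect_error(common_variance(rep(1, 5), 1:5), "zero-variance")
})

test_that("the pooled t-test matches its closed form", {
  a <- c(1.2, 0.7, 0.9, 1.4, 1.1)
  expect_equal(ttest_independent(a, a), list(t = 0, p = 1))
  set.seed(4)
  g1 <- rnorm(15); g2 <- rnorm(15, 10)  # ~10 pooled SDs apart
  expect_lt(ttest_independent(g1, g2)$p, 1e-6)
  set.seed(5)
  x <- rnorm(12, 1, 2); y <- rnorm(9, 0.2, 1.5)
  got <- ttest_independent(x, y)
  ora <- bf_pooled_t(x, y)
  expect_equal(got$t, ora$t, tolerance = 1e-9)
  expect_equal(got$p, ora$p, tolerance = 1e-6)
  expect_error(ttest_independent(1, 1:5), "at least 2")
})

test_that("the KS normality check matches a brute-force implementation", {
  set.seed(11)
  x <- rnorm(1000)
  got <- ks_normality(x)
  ora <- bf_ks_normal(x)
  expect_equal(got$D, ora$D, tolerance = 1e-9)
  expect_equal(got$p, ora$p, tolerance = 1e-6)
  expect_gt(got$p, 0.05)           # normal draws pass
  set.seed(12)
  u <- runif(1000)
  expect_lt(ks_normality(u)$p, 0.01)  # uniform draws fail
  expect_error(ks_normality(rnorm(3)), "at least 5")
})

test_that("the coordination-stiffness regression recovers exact linear structure", {
  set.seed(30)
  phase <- rnorm(30, -60, 20)
  gain <- rnorm(30, 1, 0.2)
  reg <- predict_stiffness(phase, gain, 2 * phase + 3 * gain)
  expect_equal(unname(reg$coefficients[, "estimate"]), c(0, 2, 3, 0),
               tolerance = 1e-6)
  expect_equal(reg$model_r2, 100, tolerance = 1e-9)
  # against the brute-force OLS oracle with noise
  set.seed(31)
  y <- 10 + 2 * phase + 3 * gain + 0.5 * phase * gain + rnorm(30, 0, 5)
  reg2 <- predict_stiffness(phase, gain, y)
  ora <- bf_ols(cbind(1, phase, gain, phase * gain), y)
  expect_equal(unname(reg2$coefficients[, "estimate"]), ora$beta,
               tolerance = 1e-9)
  expect_equal(unname(reg2$coefficients[, "se"]), ora$se, tolerance = 1e-9)
  expect_equal(unname(reg2$coefficients[, "p"]), ora$p, tolerance = 1e-6)
  expect_equal(reg2$collinearity_phase_gain, cor(phase, gain))
})

test_that("stiffness unrelated to coordination yields a null regression", {
  set.seed(77)
  phase <- rnorm(30, -60, 20)
  gain <- rnorm(30, 1, 0.2)
  stiffness <- rnorm(30, 124, 54)
  reg <- predict_stiffness(phase, gain, stiffness)
  expect_true(all(reg$coefficients[c("phase", "gain", "phase_x_gain"), "p"] > 0.05))
})

test_that("regression guards against underdetermined or singular designs", {
  expect_error(predict_stiffness(1:4, c(1, 2, 1, 2), 1:4), "at least 6")
  expect_error(predict_stiffness(rnorm(10), rep(1, 10), rnorm(10)),
               "rank-deficient")
})

test_that("regression confidence intervals have nominal coverage", {
  set.seed(2024)
  truth <- c(10, 2, 3, 0.5)
  hits <- 0L; total <- 0L
  for (r in 1:200) {
    phase <- rnorm(30, -60, 20)
    gain <- rnorm(30, 1, 0.2)
    y <- truth[1] + truth[2] * phase + truth[3] * gain +
      truth[4] * phase * gain + rnorm(30, 0, 8)
    reg <- predict_stiffness(phase, gain, y)
    est <- reg$coefficients[, "estimate"]
    hw <- qt(0.975, 30 - 4) * reg$coefficients[, "se"]
    hits <- hits + sum(abs(est - truth) <= hw)
    total <- total + 4L
  }
  coverage <- hits / total
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("group pooling reports per-outcome differences and keeps all rows", {
  tbl <- data.frame(group = rep(c("a", "b"), each = 5),
                    k = c(1:5, 1:5), g = c(2:6, 2:6))
  res <- pool_groups(tbl)
  expect_equal(nrow(res$pooled), 10)
  expect_true(all(res$tests$p == 1))  # identical groups
  set.seed(8)
  tbl2 <- data.frame(group = rep(c("ctl", "lbp"), each = 15),
                     k = rnorm(30, 124, 54))
  res2 <- pool_groups(tbl2)
  expect_equal(res2$n, 30)
  expect_error(pool_groups(data.frame(group = rep("a", 5), k = 1:5)),
               "two groups")
})
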