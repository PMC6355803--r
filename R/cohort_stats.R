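#' Common variance between two variables
#'
#' 100 times the squared Pearson correlation, with the correlation's
#' two-sided p-value. Symmetric in its arguments.
#'
#' @param x,y Equal-length numeric vectors (>= 3) with nonzero variance.
#' @return A list with `common_variance` (%) and `p_value`.
#' @export
common_variance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero-variance input")
  ct <- cor.test(x, y)
  list(common_variance = 100 * unname(ct$estimate)^2, p_value = ct$p.value)
}

#' Independent-samples t-test
#'
#' Two-sided two-sample Student t-test with pooled variance by default;
#' `var_equal = FALSE` gives the Welch variant.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return A list with `t` and `p`.
#' @export
ttest_independent <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 observations")
  if (var(a) == 0 && var(b) == 0) {
    # degenerate: zero spread in both groups
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic against a normal distribution with the sample
#' mean and SD, with the p-value from the asymptotic KS distribution. Because
#' the reference parameters are estimated from the sample the p-value is
#' inflated (the Lilliefors effect); `lilliefors = TRUE` applies the
#' Lilliefors correction instead (via the nortest package).
#'
#' @param x Numeric sample, n >= 5.
#' @param lilliefors Use the Lilliefors-corrected test.
#' @return A list with `D` and `p`.
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
  if (length(x) < 5) stop("need at least 5 observations for a normality check")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("the Lilliefors variant requires the nortest package")
    lt <- nortest::lillie.test(x)
    return(list(D = unname(lt$statistic), p = lt$p.value))
  }
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x), exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Predict apparent trunk stiffness from coordination
#'
#' Ordinary least-squares regression of apparent axial trunk stiffness on
#' thorax-pelvis relative phase (degrees), gain, and their interaction
#' (predictors are not centered before forming the interaction unless
#' `center = TRUE`). The phase-gain Pearson correlation is reported as a
#' collinearity diagnostic.
#'
#' @param phase Relative phase per subject, degrees.
#' @param gain Gain per subject.
#' @param stiffness Apparent axial trunk stiffness per subject (any
#'   consistent scale, e.g. body-size normalized).
#' @param center Center phase and gain before forming the interaction.
#' @return An object of class `stiffness_regression` with `coefficients`
#'   (estimate, SE, t, p per term), `model_r2` (%), `n` and
#'   `collinearity_phase_gain` (Pearson r).
#' @export
predict_stiffness <- function(phase, gain, stiffness, center = FALSE) {
  n <- length(stiffness)
  if (length(phase) != n || length(gain) != n)
    stop("phase, gain and stiffness must have the same length")
  if (n < 6) stop("need at least 6 subjects to fit 4 coefficients")
  ph <- if (center) phase - mean(phase) else phase
  ga <- if (center) gain - mean(gain) else gain
  X <- cbind(1, ph, ga, ph * ga)
  if (qr(X)$rank < 4L)
    stop("rank-deficient design: phase, gain and their interaction are collinear or constant")
  fit <- lm(stiffness ~ ph * ga)
  cf <- summary(fit)$coefficients
  rownames(cf) <- c("intercept", "phase", "gain", "phase_x_gain")
  colnames(cf) <- c("estimate", "se", "t", "p")
  structure(list(coefficients = cf,
                 model_r2 = 100 * summary(fit)$r.squared,
                 n = n,
                 collinearity_phase_gain = cor(phase, gain),
                 centered = center),
            class = "stiffness_regression")
}

#' @export
print.stiffness_regression <- function(x, ...) {
  cat(sprintf("<stiffness_regression> n = %d, R^2 = %.1f%% (phase-gain r = %.2f)\n",
              x$n, x$model_r2, x$collinearity_phase_gain))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Export a stiffness regression summary as JSON
#'
#' @param reg A `stiffness_regression`.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the JSON (e.g. normality
#'   checks).
#' @return `reg`, invisibly.
#' @export
write_regression <- function(reg, path, extra = NULL) {
  cf <- reg$coefficients
  out <- list(
    n = reg$n,
    model_r2_pct = reg$model_r2,
    collinearity_phase_gain_r = reg$collinearity_phase_gain,
    coefficients = lapply(rownames(cf), function(r)
      as.list(stats::setNames(cf[r, ], colnames(cf)))))
  names(out$coefficients) <- rownames(cf)
  if (!is.null(extra)) out <- c(out, extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(reg)
}

#' Check group differences, then pool
#'
#' Runs an independent-samples t-test per numeric outcome column between the
#' two groups, and returns the pooled table (all rows) with the
#' group-difference report attached.
#'
#' @param per_subject_table Data frame with one row per subject.
#' @param group_col Name of the group-label column; exactly two groups, each
#'   with at least 2 subjects, must be present.
#' @param var_equal Passed to [ttest_independent()].
#' @return A list with `pooled` (the input table), `tests` (data frame
#'   `variable, t, p`), `groups` and `n`.
#' @export
pool_groups <- function(per_subject_table, group_col = "group",
                        var_equal = TRUE) {
  if (!group_col %in% names(per_subject_table))
    stop("no column '", group_col, "' in the table")
  g <- factor(per_subject_table[[group_col]])
  if (nlevels(g) != 2)
    stop("exactly two groups are required, found ", nlevels(g))
  if (any(table(g) < 2)) stop("each group needs at least 2 subjects")
  num_cols <- names(per_subject_table)[vapply(per_subject_table, is.numeric, logical(1))]
  tests <- do.call(rbind, lapply(num_cols, function(v) {
    tt <- ttest_independent(per_subject_table[[v]][g == levels(g)[1]],
                            per_subject_table[[v]][g == levels(g)[2]],
                            var_equal = var_equal)
    data.frame(variable = v, t = tt$t, p = tt$p)
  }))
  list(pooled = per_subject_table, tests = tests, groups = levels(g),
       n = nrow(per_subject_table))
}
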