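# Shared fixtures: all test data are generated in code.

deg2rad <- pi / 180

# A recording whose three channels are pure sinusoids at f0 Hz.
sine_recording <- function(duration = 60, fs = 100, f0 = 0.9,
                           pelvis_amp = 4, pelvis_phase = 0,
                           thorax_amp = 4, thorax_phase = 0,
                           arm_amp = 0, arm_phase = 0, ...) {
  t <- (seq_len(duration * fs) - 1) / fs
  trajectory_recording(
    time = t,
    pelvis_angle = pelvis_amp * sin(2 * pi * f0 * t + pelvis_phase),
    thorax_angle = thorax_amp * sin(2 * pi * f0 * t + thorax_phase),
    arm_moment = arm_amp * sin(2 * pi * f0 * t + arm_phase),
    sample_rate = fs, ...)
}

# Subject configurations inside the physiological regime where thorax lags
# pelvis and the arm-swing moment dominates the damping coupling (see the
# methods vignette for the closed-form derivation of this box).
regime_subject_configs <- function(n, seed, duration = 60) {
  set.seed(seed)
  trunc_norm <- function(m, s, lo, hi) {
    x <- rnorm(1, m, s)
    while (x < lo || x > hi) x <- rnorm(1, m, s)
    x
  }
  lapply(seq_len(n), function(i) synthetic_subject_config(
    stride_frequency = runif(1, 0.8, 1.0),
    arm_amplitude = trunc_norm(9, 1, 7.5, 12),
    arm_phase_lead = trunc_norm(-90, 4, -97, -83) * pi / 180,
    truth_stiffness = trunc_norm(124, 54, 40, 280),
    truth_damping = trunc_norm(5, 2, 1, 7),
    inertia = runif(1, 0.15, 0.28),
    duration = duration, seed = seed + i))
}

# ---- independent brute-force statistical oracles ------------------------

bf_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

bf_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

bf_ks_normal <- function(x) {
  n <- length(x)
  z <- sort(x)
  F <- pnorm(z, mean(x), sd(x))
  D <- max(pmax(seq_len(n) / n - F, F - (seq_len(n) - 1) / n))
  lambda <- sqrt(n) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(1, max(0, p)))
}

bf_ols <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXi) * s2)
  t <- beta / se
  list(beta = as.numeric(beta), se = as.numeric(se),
       p = as.numeric(2 * pt(-abs(t), df)))
}

# A pair of vectors with Pearson correlation exactly r (orthonormal design).
correlated_pair <- function(r, n = 10) {
  u <- scale(seq_len(n))[, 1]
  w <- seq_len(n)^2
  w <- residuals(lm(w ~ u))
  v <- w / sqrt(sum(w^2)) * sqrt(sum(u^2))
  list(x = u, y = r * u + sqrt(1 - r^2) * v)
}
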