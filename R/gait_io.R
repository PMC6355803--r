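#' Canonical CSV column names for gait recordings
#'
#' Maps internal series names to the column names used in recording CSV files.
#' Pass a modified copy to [read_recording()] to absorb other dialects.
#'
#' @export
default_column_map <- c(
  time         = "time_s",
  pelvis_angle = "pelvis_deg",
  thorax_angle = "thorax_deg",
  arm_moment   = "arm_moment_Nm"
)

#' Construct a gait trajectory recording
#'
#' A recording holds one subject's synchronized, uniformly sampled time series:
#' axial pelvis rotation (degrees), axial thorax rotation (degrees, optional
#' for pure simulation inputs) and the arm-swing moment about the longitudinal
#' trunk axis through L5S1 (Nm, optional). Angles are stored in degrees at the
#' I/O boundary (motion-capture convention); all dynamics are computed in
#' radians internally.
#'
#' @param time Sample times in seconds; strictly increasing and uniform.
#' @param pelvis_angle Axial pelvis rotation, degrees.
#' @param thorax_angle Axial thorax rotation, degrees, or `NULL`.
#' @param arm_moment Arm-swing moment, Nm, or `NULL`.
#' @param sample_rate Sampling rate in Hz. Inferred from `time` when `NULL`.
#' @param subject_id Subject label.
#' @param group Group label (e.g. `"control"`, `"low_back_pain"`).
#' @return An object of class `trajectory_recording`.
#' @export
trajectory_recording <- function(time, pelvis_angle, thorax_angle = NULL,
                                 arm_moment = NULL, sample_rate = NULL,
                                 subject_id = "S01", group = NA_character_) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 2L) stop("a recording needs at least 2 samples")
  if (is.null(sample_rate)) sample_rate <- (n - 1) / (time[n] - time[1])
  rec <- structure(
    list(time = time,
         pelvis_angle = as.numeric(pelvis_angle),
         thorax_angle = if (!is.null(thorax_angle)) as.numeric(thorax_angle),
         arm_moment = if (!is.null(arm_moment)) as.numeric(arm_moment),
         sample_rate = as.numeric(sample_rate),
         subject_id = as.character(subject_id),
         group = as.character(group)),
    class = "trajectory_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "trajectory_recording"))
  n <- length(rec$time)
  if (n < 2L) stop("recording must contain at least 2 samples")
  if (!is.finite(rec$sample_rate) || rec$sample_rate <= 0)
    stop("sample_rate must be positive")
  for (nm in c("time", "pelvis_angle", "thorax_angle", "arm_moment")) {
    s <- rec[[nm]]
    if (is.null(s)) next
    if (length(s) != n)
      stop(sprintf("series '%s' has length %d, expected %d", nm, length(s), n))
    if (!all(is.finite(s)))
      stop(sprintf("series '%s' contains non-finite values (first at row %d)",
                   nm, which(!is.finite(s))[1]))
  }
  dt <- diff(rec$time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  dev <- abs(dt - 1 / rec$sample_rate)
  if (max(dev) >= 1e-6)
    stop(sprintf(
      "non-uniform sampling: time step at row %d deviates from 1/sample_rate by %.3g s (tolerance 1e-6)",
      which.max(dev) + 1L, max(dev)))
  invisible(rec)
}

#' @export
print.trajectory_recording <- function(x, ...) {
  cat(sprintf("<trajectory_recording> subject %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  %d samples at %g Hz (%.2f s)\n", length(x$time),
              x$sample_rate, x$time[length(x$time)] - x$time[1]))
  cat(sprintf("  series: pelvis_angle%s%s\n",
              if (is.null(x$thorax_angle)) "" else ", thorax_angle",
              if (is.null(x$arm_moment)) "" else ", arm_moment"))
  invisible(x)
}

#' @export
as.data.frame.trajectory_recording <- function(x, ...) {
  df <- data.frame(time_s = x$time, pelvis_deg = x$pelvis_angle)
  if (!is.null(x$thorax_angle)) df$thorax_deg <- x$thorax_angle
  if (!is.null(x$arm_moment)) df$arm_moment_Nm <- x$arm_moment
  df
}

#' Read a gait recording from CSV
#'
#' @param path CSV file with a header row, one row per sample.
#' @param column_map Named character vector mapping internal names
#'   (`time`, `pelvis_angle`, `thorax_angle`, `arm_moment`) to file columns;
#'   see [default_column_map]. Units are taken as declared: seconds, degrees,
#'   degrees, Nm.
#' @param subject_id,group Labels attached to the recording; `subject_id`
#'   defaults to the file name without extension.
#' @return A validated [trajectory_recording()].
#' @export
read_recording <- function(path, column_map = default_column_map,
                           subject_id = NULL, group = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  for (nm in c("time", "pelvis_angle")) {
    if (!column_map[[nm]] %in% names(df))
      stop(sprintf("missing required column '%s' in %s", column_map[[nm]], path))
  }
  get <- function(nm) {
    col <- column_map[[nm]]
    if (!is.null(col) && !is.na(col) && col %in% names(df)) df[[col]] else NULL
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  trajectory_recording(time = get("time"), pelvis_angle = get("pelvis_angle"),
                       thorax_angle = get("thorax_angle"),
                       arm_moment = get("arm_moment"),
                       subject_id = subject_id, group = group)
}

#' Write a gait recording to CSV
#'
#' Writes the canonical columns (`time_s, pelvis_deg, thorax_deg,
#' arm_moment_Nm`), omitting series that are absent, at full double precision
#' so that `read_recording(write_recording(x))` round-trips within 1e-9.
#'
#' @param rec A [trajectory_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  df <- as.data.frame(rec)
  df[] <- lapply(df, function(col) formatC(col, digits = 17, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct subject anthropometrics
#'
#' @param height Stature, m.
#' @param mass Body mass, kg.
#' @param thorax_circumference Thorax circumference, m (optional; used by the
#'   cylinder inertia model).
#' @param thorax_length Thorax segment length, m (optional; accepted for
#'   completeness, unused by the cylinder inertia model).
#' @param thorax_inertia Direct override for thorax axial inertia, kg m^2.
#' @param group Group label.
#' @return An object of class `subject_anthropometrics`.
#' @export
subject_anthropometrics <- function(height, mass, thorax_circumference = NULL,
                                    thorax_length = NULL, thorax_inertia = NULL,
                                    group = NA_character_) {
  if (!is.finite(height) || height <= 0.5 || height >= 2.6)
    stop("height must lie in (0.5, 2.6) m")
  if (!is.finite(mass) || mass <= 20 || mass >= 250)
    stop("mass must lie in (20, 250) kg")
  for (nm in c("thorax_circumference", "thorax_length", "thorax_inertia")) {
    v <- get(nm)
    if (!is.null(v) && (!is.finite(v) || v <= 0))
      stop(nm, " must be a positive finite number")
  }
  structure(list(height = height, mass = mass,
                 thorax_circumference = thorax_circumference,
                 thorax_length = thorax_length,
                 thorax_inertia = thorax_inertia,
                 group = as.character(group)),
            class = "subject_anthropometrics")
}

#' Read anthropometrics from JSON
#'
#' Expects keys `height_m, mass_kg` and optionally `thorax_circumference_m,
#' thorax_length_m, thorax_inertia_kgm2, group`.
#'
#' @param path JSON file.
#' @return A [subject_anthropometrics()] object.
#' @export
read_anthropometrics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject_anthropometrics(
    height = x$height_m, mass = x$mass_kg,
    thorax_circumference = x$thorax_circumference_m,
    thorax_length = x$thorax_length_m,
    thorax_inertia = x$thorax_inertia_kgm2,
    group = if (is.null(x$group)) NA_character_ else x$group)
}

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward, so the output has no
#' phase shift at any frequency. Edge transients are suppressed by
#' odd-reflection padding combined with steady-state initial filter
#' conditions, so a constant input is returned unchanged.
#'
#' @param series Numeric samples.
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz; must lie in (0, sample_rate/2).
#' @param order Butterworth order of each pass (default 2).
#' @return Filtered series, same length.
#' @export
lowpass_filter <- function(series, sample_rate, cutoff, order = 2) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  bf <- signal::butter(order, 2 * cutoff / sample_rate, type = "low")
  b <- bf$b
  a <- bf$a
  m <- max(length(a), length(b)) - 1L
  padlen <- 3L * (length(a) + length(b))
  if (length(series) <= padlen)
    stop(sprintf("series too short for filtering: need > %d samples", padlen))
  zi <- lfilter_zi(b, a)
  ext <- c(2 * series[1] - series[(padlen + 1L):2L],
           series,
           2 * series[length(series)] -
             series[(length(series) - 1L):(length(series) - padlen)])
  y <- iir_filter_zi(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_zi(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + length(series))]
}

# Steady-state initial conditions of the direct-form II transposed filter
# (the step-response state), so filtering a constant produces that constant.
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  bc <- c(b, rep(0, m + 1L - length(b)))
  ac <- c(a, rep(0, m + 1L - length(a)))
  g <- sum(bc) / sum(ac)  # DC gain
  # z_j = b_j - a_j * g + z_{j+1} for unit-step input at steady state
  rev(cumsum(rev(bc[-1L] - ac[-1L] * g)))
}

#' Numerical differentiation by central differences
#'
#' Central differences on the interior with one-sided differences at the
#' endpoints (so the output keeps the input length). `order = 2` applies the
#' first-order operator twice.
#'
#' @param series Numeric samples.
#' @param sample_rate Sampling rate, Hz.
#' @param order Derivative order, 1 or 2.
#' @return Derivative series, same length, units per second (or second^2).
#' @export
differentiate <- function(series, sample_rate, order = 1) {
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  min_len <- if (order == 1) 3L else 5L
  if (length(series) < min_len)
    stop(sprintf("series too short to differentiate: need >= %d samples", min_len))
  d <- pracma::gradient(series, h1 = 1 / sample_rate)
  if (order == 2) d <- pracma::gradient(d, h1 = 1 / sample_rate)
  d
}
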