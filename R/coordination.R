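#' One-sided periodogram
#'
#' Raw (untapered, unsmoothed) periodogram of the mean-removed series, with
#' frequency resolution `sample_rate / length(series)`.
#'
#' @param series Numeric samples, length >= 16.
#' @param sample_rate Hz.
#' @return A list with `frequency` (Hz) and `power`.
#' @export
power_spectrum <- function(series, sample_rate) {
  if (length(series) < 16) stop("series too short for a power spectrum (need >= 16)")
  sp <- spec.pgram(series - mean(series), taper = 0, detrend = FALSE,
                   demean = FALSE, fast = FALSE, plot = FALSE)
  list(frequency = sp$freq * sample_rate, power = sp$spec)
}

#' Detect the stride frequency from pelvis rotations
#'
#' The stride frequency is the local peak of the pelvis-rotation power
#' spectrum closest to 1 Hz. Local maxima are defined on the periodogram grid
#' (strictly greater than both neighbours); peaks below `prominence` times
#' the maximum band power are rejected as noise bumps; among qualifying peaks
#' within `search_band` the frequency minimizing `|f - 1|` is returned,
#' regardless of relative power.
#'
#' @param pelvis Pelvis rotation series, degrees.
#' @param sample_rate Hz.
#' @param search_band Frequency band searched, Hz.
#' @param prominence Rejection floor as a fraction of maximum band power.
#' @return Stride frequency, Hz.
#' @export
stride_frequency <- function(pelvis, sample_rate, search_band = c(0.5, 1.5),
                             prominence = 0.05) {
  ps <- power_spectrum(pelvis, sample_rate)
  f <- ps$frequency; p <- ps$power
  n <- length(p)
  local_max <- c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n], FALSE)
  in_band <- f > search_band[1] & f < search_band[2]
  if (!any(in_band)) stop("search band contains no frequency bins")
  floor_p <- prominence * max(p[in_band])
  cand <- which(local_max & in_band & p > floor_p)
  if (length(cand) == 0)
    stop("no qualifying spectral peak in the search band: signal has no stride rhythm")
  f[cand[which.min(abs(f[cand] - 1))]]
}

#' Frequency response from pelvis to thorax at one frequency
#'
#' Single-frequency Fourier coefficients of both mean-removed series are
#' evaluated over the largest prefix containing an integer number of cycles
#' of `freq` (integer-cycle truncation removes leakage bias). The transfer is
#' `H = C_thorax / C_pelvis`; the gain is `|H|` and the relative phase
#' `Arg(H)` in degrees wrapped to (-180, 180], so a thorax lag yields a
#' negative phase.
#'
#' @param pelvis,thorax Equal-length series (degrees; the result is invariant
#'   to units and offsets).
#' @param sample_rate Hz.
#' @param freq Evaluation frequency, Hz; the record must contain at least two
#'   full cycles.
#' @return A list with `relative_phase` (deg) and `gain`.
#' @export
frf_at_frequency <- function(pelvis, thorax, sample_rate, freq) {
  n <- length(pelvis)
  if (length(thorax) != n) stop("pelvis and thorax must have the same length")
  n_cyc <- floor((n / sample_rate) * freq + 1e-9)
  if (n_cyc < 2) stop("record too short: need at least 2 cycles at the evaluation frequency")
  len <- floor(n_cyc * sample_rate / freq + 1e-9)
  len <- min(len, n)
  t <- (seq_len(len) - 1) / sample_rate
  basis <- exp(-2i * pi * freq * t)
  cp <- sum((pelvis[seq_len(len)] - mean(pelvis[seq_len(len)])) * basis) / len
  ct <- sum((thorax[seq_len(len)] - mean(thorax[seq_len(len)])) * basis) / len
  if (Mod(cp) < 1e-12)
    stop("pelvis Fourier coefficient is numerically zero at this frequency; the transfer is undefined")
  H <- ct / cp
  ph <- Arg(H) * 180 / pi
  # keep the wrap in (-180, 180]: an exact anti-phase ratio may land on -180
  # through floating-point rounding of a zero imaginary part
  if (ph <= -180 + 1e-9) ph <- ph + 360
  list(relative_phase = ph, gain = Mod(H))
}

#' Thorax-pelvis coordination metrics for one recording
#'
#' Detects the stride frequency from the pelvis series, then evaluates the
#' pelvis-to-thorax frequency response at that frequency.
#'
#' @param rec A [trajectory_recording()] with pelvis and thorax series.
#' @param search_band,prominence Passed to [stride_frequency()].
#' @return An object of class `coordination_metrics` with `stride_frequency`
#'   (Hz), `relative_phase` (deg, negative = thorax lags pelvis) and `gain`.
#' @export
coordination_metrics <- function(rec, search_band = c(0.5, 1.5),
                                 prominence = 0.05) {
  validate_recording(rec)
  if (is.null(rec$thorax_angle))
    stop("recording has no thorax_angle series; cannot compute coordination")
  f0 <- stride_frequency(rec$pelvis_angle, rec$sample_rate, search_band, prominence)
  frf <- frf_at_frequency(rec$pelvis_angle, rec$thorax_angle, rec$sample_rate, f0)
  structure(list(stride_frequency = f0,
                 relative_phase = frf$relative_phase,
                 gain = frf$gain,
                 subject_id = rec$subject_id,
                 group = rec$group),
            class = "coordination_metrics")
}

#' @export
print.coordination_metrics <- function(x, ...) {
  cat(sprintf("<coordination_metrics> subject %s: f0 = %.3f Hz, phase = %.1f deg, gain = %.3f\n",
              x$subject_id, x$stride_frequency, x$relative_phase, x$gain))
  invisible(x)
}

#' Circular mean of phase angles in degrees
#'
#' Averages phases on the circle (resultant-vector direction), appropriate
#' for cohort summaries of relative phases that may straddle the +-180 wrap.
#'
#' @param phases_deg Phase angles, degrees.
#' @return Mean phase in (-180, 180].
#' @export
circular_mean_deg <- function(phases_deg) {
  Arg(mean(exp(1i * phases_deg * pi / 180))) * 180 / pi
}

#' Export coordination metrics as CSV
#'
#' @param metrics List of `coordination_metrics` objects.
#' @param path Output CSV path.
#' @return The table written, invisibly.
#' @export
write_coordination <- function(metrics, path) {
  df <- do.call(rbind, lapply(metrics, function(m) data.frame(
    subject_id = m$subject_id, group = m$group,
    stride_frequency_hz = m$stride_frequency,
    relative_phase_deg = m$relative_phase, gain = m$gain)))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
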