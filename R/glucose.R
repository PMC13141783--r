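# Cleaning of continuous glucose traces and glycemic-excursion metrics.
#
# Two documented processing branches share the despiked, median-filtered
# series:
#   * metrics branch: 60-s causal moving average, baseline median over
#     [-25, 0] min -> delta_g (ΔG(t)), used for peak/half-max/iAUC;
#   * onset branch: baseline median over [-5, 0] min, 2-min causal boxcar,
#     smoothed finite-difference derivative, used by the two-threshold
#     sustained onset detector (and for all derivative-based metrics).

#' Preprocess a continuous glucose trace
#'
#' Applies MAD despiking (k = 2), a 7-sample centered median filter and a
#' 60-sample causal moving average, then subtracts the baseline median
#' over the pre-event window to give the excursion `delta_g` (ΔG(t),
#' mg/dL above baseline). The derivative branch subtracts the -5..0 min
#' baseline median, smooths with a 2-min causal boxcar, and takes a
#' smoothed (60-sample) finite-difference derivative in mg/dL per second.
#'
#' @param raw A `uniform_trace` of glucose in mg/dL spanning at least
#'   -25 to +90 min.
#' @param config A configuration list, see [default_config()]; the
#'   `glucose` entry holds all tunables.
#' @return An object of class `glucose_trace` with elements `raw` (input),
#'   `clean` (despiked + median filtered), `delta_g`, `raw_delta`
#'   (despiked-but-unsmoothed baseline-subtracted series, used for
#'   interpolated half-max timing), `level_onset` (onset-branch level
#'   series `y0`, unsmoothed), `level_onset_smooth` (2-min boxcar of
#'   `y0`), `derivative`, and `baseline_value` (mg/dL).
#' @export
preprocess_glucose <- function(raw, config = default_config()) {
  stopifnot(inherits(raw, "uniform_trace"))
  gc <- config$glucose
  tt <- trace_times(raw)
  need <- c(gc$baseline_window_s[1], gc$post_window_s[2])
  if (tt[1] > need[1] + 1e-9 || tt[length(tt)] < need[2] - 1e-9)
    stop(sprintf(
      "glucose trace spans [%.0f, %.0f] s but [%.0f, %.0f] s is required",
      tt[1], tt[length(tt)], need[1], need[2]))
  clean <- median_filter_centered(despike_mad(raw, k = gc$despike_k,
                                              local_window = gc$despike_local_window),
                                  window = gc$median_window)
  level <- causal_moving_average(clean, window = gc$smooth_window)
  delta_g <- baseline_subtract(level, gc$baseline_window_s)
  raw_delta <- baseline_subtract(clean, gc$baseline_window_s)

  # Onset branch: short local baseline; the level condition tests the
  # unsmoothed y0 itself (the 1-min sustain supplies the noise rejection),
  # while the derivative comes from the 2-min boxcar-smoothed level.
  y0 <- baseline_subtract(clean, gc$onset_baseline_window_s)
  y0s <- causal_moving_average(y0, window = gc$onset_boxcar_window)
  deriv <- finite_difference_derivative(y0s, smooth_window = gc$smooth_window)

  structure(
    list(raw = raw, clean = clean, delta_g = delta_g, raw_delta = raw_delta,
         level_onset = y0, level_onset_smooth = y0s, derivative = deriv,
         baseline_value = attr(delta_g, "baseline_value")),
    class = "glucose_trace")
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> baseline %.1f mg/dL, %d samples\n",
              x$baseline_value, length(x$raw$values)))
  invisible(x)
}

#' Robust onset thresholds from the pre-event segment
#'
#' Computes, from t < 0 samples only, the robust center and scale of the
#' onset-branch derivative (median `m_d`, scaled MAD `sigma_d`) and the
#' scaled MAD `sigma_y` of the onset-branch level, then forms
#' `T_slope = m_d + z * sigma_d` and `T_level = z * sigma_y`.
#'
#' @param g A `glucose_trace`.
#' @param z Threshold multiplier (default 3).
#' @return A list of class `onset_thresholds` with `m_d`, `sigma_d`,
#'   `sigma_y`, `z`, `t_slope`, `t_level`.
#' @export
onset_thresholds <- function(g, z = 3) {
  stopifnot(inherits(g, "glucose_trace"))
  pre_d <- g$derivative$values[trace_times(g$derivative) < 0]
  pre_y <- g$level_onset$values[trace_times(g$level_onset) < 0]
  if (length(pre_d) < 2L || length(pre_y) < 2L)
    stop("no pre-event segment available for threshold estimation")
  m_d <- stats::median(pre_d)
  sigma_d <- robust_mad_scale(pre_d)
  sigma_y <- robust_mad_scale(pre_y)
  structure(list(m_d = m_d, sigma_d = sigma_d, sigma_y = sigma_y, z = z,
                 t_slope = m_d + z * sigma_d, t_level = z * sigma_y),
            class = "onset_thresholds")
}

#' Sustained two-threshold blood-glucose onset detector
#'
#' Marks samples at t >= 0 where either the smoothed derivative exceeds
#' the slope threshold or the onset-branch level exceeds the level
#' threshold, and declares onset at the first sample beginning a run of at
#' least `sustain` consecutive marked samples (1 min of continuous
#' evidence at 1 Hz).
#'
#' @param g A `glucose_trace`.
#' @param thresholds An `onset_thresholds` object computed from the same
#'   trace's pre-event segment.
#' @param sustain Required run length in seconds (default 60).
#' @return Onset time in seconds, or `NA_real_` when no sustained run
#'   exists (absence is a value, not an error).
#' @export
detect_bg_onset <- function(g, thresholds = onset_thresholds(g),
                            sustain = 60) {
  stopifnot(inherits(g, "glucose_trace"),
            inherits(thresholds, "onset_thresholds"))
  sustain <- as.integer(round(sustain * g$raw$fs))
  if (sustain < 1L) stop("sustain must be at least one sample")
  tt <- trace_times(g$derivative)
  post <- tt >= 0
  cond <- (g$derivative$values > thresholds$t_slope) |
    (g$level_onset$values > thresholds$t_level)
  cond <- cond & post
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= sustain)
  if (length(ok) == 0L) return(NA_real_)
  tt[starts[ok[1]]]
}

#' Positive-only incremental area under the excursion
#'
#' Trapezoidal integral of `max(delta_g, 0)` over the post-delivery window,
#' in mg/dL x min.
#'
#' @param g A `glucose_trace`.
#' @param window Numeric `c(t_start, t_end)` in seconds (default 0-90 min).
#' @return iAUC in mg/dL x min.
#' @export
iauc_positive <- function(g, window = c(0, 5400)) {
  stopifnot(inherits(g, "glucose_trace"))
  idx <- window_indices(g$delta_g, window[1], window[2])
  if (length(idx) < 2L) stop("iAUC window lies outside the trace")
  tt <- trace_times(g$delta_g)[idx] / 60
  y <- pmax(g$delta_g$values[idx], 0)
  pracma::trapz(tt, y)
}

#' Glycemic-excursion summary metrics
#'
#' Computes, from a preprocessed glucose trace and a detected onset time:
#' the peak excursion within 0-90 min and its time; the peak derivative in
#' the early 0-30 min window and its time; the half-max recovery time
#' (first post-peak crossing of half the peak, linearly interpolated on
#' the despiked-but-unsmoothed baseline-subtracted series); a plateau
#' interval (first post-peak-derivative interval where the smoothed
#' derivative stays within a band of +/- `plateau_band_frac` times the
#' peak rise derivative for at least `plateau_sustain_s`); the return to
#' baseline (the earlier of the first ΔG <= 0 after the peak and the first
#' sustained relaxation of the derivative above `-plateau_band_frac` times
#' the peak rise derivative after decline began); the most negative
#' post-peak derivative (rate of fall); and the positive-only iAUC.
#'
#' @param g A `glucose_trace`.
#' @param onset Onset time in seconds (`NA` allowed; timing metrics are
#'   still computed relative to the trace, onset is merely reported).
#' @param config Configuration list (entry `glucose`).
#' @return A list of class `glucose_metrics`; `NA` marks absent events.
#' @export
excursion_summary <- function(g, onset = NA_real_,
                              config = default_config()) {
  stopifnot(inherits(g, "glucose_trace"))
  gc <- config$glucose
  post <- gc$post_window_s

  # Peak excursion in 0-90 min.
  idx_peak <- window_indices(g$delta_g, post[1], post[2])
  tt_dg <- trace_times(g$delta_g)
  i_pk <- idx_peak[which.max(g$delta_g$values[idx_peak])]
  peak_dg <- g$delta_g$values[i_pk]
  peak_time <- tt_dg[i_pk]

  # Peak derivative in the early window (0-30 min).
  tt_d <- trace_times(g$derivative)
  idx_early <- window_indices(g$derivative, gc$early_deriv_window_s[1],
                              gc$early_deriv_window_s[2])
  i_pd <- idx_early[which.max(g$derivative$values[idx_early])]
  peak_deriv <- g$derivative$values[i_pd]
  peak_deriv_time <- tt_d[i_pd]

  # Rate of fall: most negative derivative after the excursion peak.
  idx_fall <- which(tt_d > peak_time & tt_d <= post[2])
  fall_deriv <- if (length(idx_fall)) min(g$derivative$values[idx_fall])
                else NA_real_
  fall_deriv_time <- if (length(idx_fall))
    tt_d[idx_fall[which.min(g$derivative$values[idx_fall])]] else NA_real_

  half_max_time <- half_crossing_time(g$raw_delta, peak_time,
                                      0.5 * peak_dg, post[2])

  band <- gc$plateau_band_frac * peak_deriv
  sustain_n <- as.integer(round(gc$plateau_sustain_s * g$raw$fs))
  plateau <- first_sustained_run(
    tt_d, abs(g$derivative$values) <= band & tt_d > peak_deriv_time,
    sustain_n)
  plateau_interval <- if (is.na(plateau)) c(NA_real_, NA_real_)
                      else c(plateau, plateau + gc$plateau_sustain_s)

  # Return to baseline: amplitude criterion or sustained derivative
  # relaxation after decline began (decline start = excursion peak).
  i_amp <- which(tt_dg > peak_time & g$delta_g$values <= 0)
  t_amp <- if (length(i_amp)) tt_dg[i_amp[1]] else NA_real_
  i_decl <- which(tt_d > peak_time & g$derivative$values < -band)
  relax <- if (length(i_decl))
    first_sustained_run(
      tt_d, g$derivative$values >= -band & tt_d > tt_d[i_decl[1]], sustain_n)
  else NA_real_
  return_time <- suppressWarnings(min(t_amp, relax, na.rm = TRUE))
  if (!is.finite(return_time)) return_time <- NA_real_

  structure(
    list(onset_time_s = onset,
         peak_delta_g = peak_dg, peak_time_s = peak_time,
         peak_derivative = peak_deriv, peak_derivative_time_s = peak_deriv_time,
         fall_derivative = fall_deriv, fall_derivative_time_s = fall_deriv_time,
         half_max_return_time_s = half_max_time,
         plateau_interval_s = plateau_interval,
         return_to_baseline_time_s = return_time,
         iauc = iauc_positive(g, post),
         baseline_value = g$baseline_value),
    class = "glucose_metrics")
}

# First time at which `cond` starts a run of >= sustain_n TRUEs.
first_sustained_run <- function(tt, cond, sustain_n) {
  cond[is.na(cond)] <- FALSE
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= sustain_n)
  if (length(ok) == 0L) return(NA_real_)
  tt[starts[ok[1]]]
}

# Linearly interpolated first downward crossing of `level` after t_peak.
half_crossing_time <- function(trace, t_peak, level, t_max) {
  tt <- trace_times(trace)
  idx <- which(tt > t_peak & tt <= t_max)
  if (length(idx) < 2L) return(NA_real_)
  y <- trace$values[idx]
  below <- which(y <= level)
  if (length(below) == 0L) return(NA_real_)
  j <- below[1]
  if (j == 1L) return(tt[idx[1]])
  i0 <- idx[j - 1L]; i1 <- idx[j]
  y0 <- trace$values[i0]; y1 <- trace$values[i1]
  if (y0 == y1) return(tt[i1])
  tt[i0] + (level - y0) / (y1 - y0) * (tt[i1] - tt[i0])
}

#' One-row data frame of glucose metrics
#'
#' @param m A `glucose_metrics` object.
#' @return A one-row `data.frame` with documented column names; times in
#'   seconds, amplitudes in mg/dL, derivatives in mg/dL per second, iAUC
#'   in mg/dL x min.
#' @export
glucose_metrics_row <- function(m) {
  stopifnot(inherits(m, "glucose_metrics"))
  data.frame(
    bg_onset_s = m$onset_time_s,
    bg_peak_delta_g_mg_dl = m$peak_delta_g,
    bg_peak_time_s = m$peak_time_s,
    bg_peak_derivative_mg_dl_s = m$peak_derivative,
    bg_peak_derivative_time_s = m$peak_derivative_time_s,
    bg_fall_derivative_mg_dl_s = m$fall_derivative,
    bg_half_max_return_s = m$half_max_return_time_s,
    bg_plateau_start_s = m$plateau_interval_s[1],
    bg_return_to_baseline_s = m$return_to_baseline_time_s,
    bg_iauc_mg_dl_min = m$iauc,
    bg_baseline_mg_dl = m$baseline_value)
}
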