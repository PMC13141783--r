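# Photometry preprocessing (reference regression, robust filtering,
# baseline z-score) and per-session response metrics: peak z, clipped and
# total AUCs, spectral band-power onset against a jittered pseudo-event
# null, and the aperiodic 1/f spectral exponent of the baseline.

#' Preprocess a photometry session
#'
#' Regresses the isosbestic reference out of the signal channel, then
#' applies MAD despiking (k = 2), a 7-sample centered median filter, a
#' 60-sample causal moving average and a zero-phase Butterworth low-pass
#' (4-min cutoff period, order 3), and finally z-scores within the
#' baseline window, yielding Z_FP(t) with mean 0 and unit SD at baseline.
#'
#' @param sig Signal channel (465 nm), a `uniform_trace`.
#' @param reference Isosbestic reference channel (405 nm), aligned.
#' @param config Configuration list (entry `photometry`).
#' @param label Session identifier used in error messages.
#' @return An object of class `photometry_trace` with elements `z`
#'   (Z_FP(t)), `corrected` (reference-regressed raw signal) and
#'   `degenerate` (TRUE when the corrected signal has essentially no
#'   variance, e.g. signal equal to reference).
#' @export
preprocess_photometry <- function(sig, reference, config = default_config(),
                                  label = "session") {
  pc <- config$photometry
  corrected <- regress_out_reference(sig, reference)
  degenerate <- stats::sd(corrected$values) <
    1e-9 * (stats::sd(sig$values) + 1e-12)
  x <- despike_mad(corrected, k = pc$despike_k,
                   local_window = pc$despike_local_window)
  x <- median_filter_centered(x, window = pc$median_window)
  x <- causal_moving_average(x, window = pc$smooth_window)
  x <- lowpass_zero_phase(x, cutoff_period_min = pc$lowpass_period_min,
                          order = pc$lowpass_order)
  z <- zscore_baseline(x, pc$baseline_window_s, label = label)
  structure(list(z = z, corrected = corrected, degenerate = degenerate),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %d samples%s\n", length(x$z$values),
              if (x$degenerate) " (degenerate: signal = reference)" else ""))
  invisible(x)
}

#' Extremal z response in an early window
#'
#' Returns the extremum of Z_FP over a window in the requested direction
#' (`"inhibition"` = most negative, `"excitation"` = most positive) and
#' its time. Both the 0-15 min and 0-10 min conventions in use are
#' supported through `window`. Ties resolve to the earliest sample.
#'
#' @param fp A `photometry_trace`.
#' @param window Numeric `c(t_start, t_end)` in seconds (default 0-15 min).
#' @param direction `"inhibition"` or `"excitation"`.
#' @return Named list `value` (z) and `time_s`.
#' @export
peak_z_response <- function(fp, window = c(0, 900),
                            direction = c("inhibition", "excitation")) {
  stopifnot(inherits(fp, "photometry_trace"))
  direction <- match.arg(direction)
  idx <- window_indices(fp$z, window[1], window[2])
  if (length(idx) == 0L) stop("window lies outside the trace")
  v <- fp$z$values[idx]
  j <- if (direction == "inhibition") which.min(v) else which.max(v)
  list(value = v[j], time_s = trace_times(fp$z)[idx[j]])
}

#' Negative-only AUC of the z trace
#'
#' Trapezoidal integral of `min(Z, 0)` from t = 0 to `t_end` (typically
#' the time of peak blood glucose), in z x min; reflects only deflections
#' below baseline.
#'
#' @param fp A `photometry_trace`.
#' @param t_end End of integration in seconds (> 0).
#' @return AUC in z x min (<= 0).
#' @export
negative_auc <- function(fp, t_end) {
  stopifnot(inherits(fp, "photometry_trace"))
  if (is.na(t_end))
    stop("t_end is absent (no blood-glucose peak); use total_auc instead")
  if (t_end <= 0) stop("t_end must be positive")
  idx <- window_indices(fp$z, 0, t_end)
  tt <- trace_times(fp$z)[idx] / 60
  pracma::trapz(tt, pmin(fp$z$values[idx], 0))
}

#' Positive-only AUC of the z trace
#'
#' Counterpart of [negative_auc()]: integral of `max(Z, 0)` over the same
#' window, so that the negative and positive parts sum to the unclipped
#' integral.
#'
#' @inheritParams negative_auc
#' @return AUC in z x min (>= 0).
#' @export
positive_auc <- function(fp, t_end) {
  stopifnot(inherits(fp, "photometry_trace"))
  if (is.na(t_end) || t_end <= 0) stop("t_end must be positive")
  idx <- window_indices(fp$z, 0, t_end)
  tt <- trace_times(fp$z)[idx] / 60
  pracma::trapz(tt, pmax(fp$z$values[idx], 0))
}

#' Total AUC of the unmodified z trace
#'
#' Trapezoidal integral of Z from t = 0 to the end of the session (or
#' `t_end` when given), without clipping.
#'
#' @param fp A `photometry_trace`.
#' @param t_end Optional end time in seconds; defaults to the last sample.
#' @return AUC in z x min.
#' @export
total_auc <- function(fp, t_end = NULL) {
  stopifnot(inherits(fp, "photometry_trace"))
  tt_all <- trace_times(fp$z)
  if (is.null(t_end)) t_end <- tt_all[length(tt_all)]
  idx <- window_indices(fp$z, 0, t_end)
  tt <- tt_all[idx] / 60
  pracma::trapz(tt, fp$z$values[idx])
}

# Hann-tapered segmented band-power series: one-sided PSD averaged over
# the frequency band, at segment-center times. Returns bin centers (s)
# and band power.
stft_band_power <- function(x, fs, t0, window_n, step_n, band_hz) {
  n <- length(x)
  if (n < window_n) stop("trace shorter than one spectrogram window")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(window_n) / (window_n + 1))) # Hann
  u <- sum(w^2)
  starts <- seq(1L, n - window_n + 1L, by = step_n)
  freqs <- (seq_len(window_n) - 1) / window_n * fs
  keep <- which(freqs >= band_hz[1] - 1e-12 & freqs <= band_hz[2] + 1e-12)
  if (length(keep) == 0L) stop("no spectrogram frequency bin in the band")
  p <- vapply(starts, function(s) {
    seg <- x[s:(s + window_n - 1L)]
    sp <- abs(stats::fft(w * (seg - mean(seg))))^2 / (fs * u)
    mean(2 * sp[keep]) # one-sided
  }, numeric(1))
  centers <- t0 + (starts - 1 + (window_n - 1) / 2) / fs
  list(time_s = centers, power = p)
}

#' Band-power onset of the low-frequency photometry response
#'
#' Computes a Hann-tapered spectrogram of Z_FP (20-min windows, 99%
#' overlap), averages the one-sided PSD over the slow band (periods 14-20
#' min, i.e. 0.05-0.071 cycles/min), and compares the band power at each
#' time bin around the true event with the same quantity aligned to
#' `n_null` pseudo-onset times drawn uniformly (without replacement) over
#' in-session times where the full detection window fits, excluding a
#' guard around the true event. The per-bin rank p-value is
#' `p = (1 + #(null >= real)) / (n_null + 1)`; the onset is the first bin
#' in the detection window with `p < alpha`.
#'
#' @param fp A `photometry_trace`.
#' @param config Configuration list (entry `spectral`); tunables: band in
#'   cycles/min, spectrogram window and overlap, null count, guard,
#'   detection window, alpha.
#' @param seed Integer seed for the pseudo-onset draw.
#' @return A list of class `spectral_onset` with `time_s` (bin offsets τ
#'   relative to the event), `p_real`, `p_value`, `onset_s` (first
#'   significant bin or `NA`), `n_null`, `alpha`.
#' @export
band_power_onset <- function(fp, config = default_config(), seed = 1L) {
  stopifnot(inherits(fp, "photometry_trace"))
  sc <- config$spectral
  z <- fp$z
  fs <- z$fs
  window_n <- as.integer(round(sc$window_min * 60 * fs))
  step_n <- max(1L, as.integer(round(window_n * (1 - sc$overlap))))
  band_hz <- sc$band_cpm / 60
  if (sc$n_null < 20L) stop("n_null must be >= 20 for usable p resolution")
  bp <- stft_band_power(z$values, fs, z$t0, window_n, step_n, band_hz)

  detect <- sc$detect_window_s
  # Power at offsets tau relative to an alignment time, by nearest bin.
  tau_grid <- bp$time_s[bp$time_s >= detect[1] - 1e-9 &
                        bp$time_s <= detect[2] + 1e-9]
  if (length(tau_grid) == 0L)
    stop("session too short: no spectrogram bin inside the detection window")
  nearest_power <- function(times) {
    idx <- findInterval(times, bp$time_s, all.inside = TRUE)
    idx2 <- pmin(idx + 1L, length(bp$time_s))
    use2 <- abs(bp$time_s[idx2] - times) < abs(bp$time_s[idx] - times)
    bp$power[ifelse(use2, idx2, idx)]
  }
  p_real <- nearest_power(tau_grid)

  # Admissible pseudo-onset times: full detection window inside the bin
  # range, outside the guard around the true event.
  lo <- bp$time_s[1] - detect[1]
  hi <- bp$time_s[length(bp$time_s)] - detect[2]
  cand <- seq(ceiling(lo), floor(hi), by = 1 / fs)
  cand <- cand[abs(cand) > sc$guard_min * 60]
  if (length(cand) < sc$n_null)
    stop("session too short for ", sc$n_null, " pseudo-onsets")
  set.seed(seed)
  pseudo <- sample(cand, sc$n_null, replace = FALSE)
  null_mat <- vapply(pseudo, function(t_k) nearest_power(t_k + tau_grid),
                     numeric(length(tau_grid)))
  exceed <- rowSums(null_mat >= matrix(p_real, nrow = length(tau_grid),
                                       ncol = sc$n_null))
  p_value <- (1 + exceed) / (sc$n_null + 1)
  sig <- which(p_value < sc$alpha)
  structure(
    list(time_s = tau_grid, p_real = p_real, p_value = p_value,
         onset_s = if (length(sig)) tau_grid[sig[1]] else NA_real_,
         n_null = sc$n_null, alpha = sc$alpha),
    class = "spectral_onset")
}

#' Aperiodic 1/f spectral exponent of the baseline
#'
#' Estimates the Welch power spectral density of Z_FP over the baseline
#' window (Hann taper, 20-min segments, 50% overlap) and fits a line to
#' log10(PSD) vs log10(f) over the fit band (0.05-0.5 cycles/min by
#' default, excluding DC and near-Nyquist frequencies). The exponent
#' kappa is the negative slope: larger kappa means a stronger
#' low-frequency bias.
#'
#' @param fp A `photometry_trace`.
#' @param baseline_window Numeric `c(t_start, t_end)` in seconds; must span
#'   at least 20 min.
#' @param config Configuration list (entry `spectral`; `psd_fit_band_cpm`).
#' @return A list with `kappa`, `freq_cpm`, `psd` (fit band only).
#' @export
psd_aperiodic_slope <- function(fp, baseline_window = c(-1500, 0),
                                config = default_config()) {
  stopifnot(inherits(fp, "photometry_trace"))
  sc <- config$spectral
  z <- trace_slice(fp$z, baseline_window[1], baseline_window[2])
  fs <- z$fs
  n <- length(z$values)
  if (n < 20 * 60 * fs) stop("baseline must span at least 20 min")
  seg_n <- min(as.integer(round(sc$window_min * 60 * fs)), n)
  step_n <- max(1L, seg_n %/% 2L)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_n) / (seg_n + 1)))
  u <- sum(w^2)
  starts <- seq(1L, n - seg_n + 1L, by = step_n)
  psd <- rowMeans(vapply(starts, function(s) {
    seg <- z$values[s:(s + seg_n - 1L)]
    abs(stats::fft(w * (seg - mean(seg))))^2 / (fs * u)
  }, numeric(seg_n)))
  freqs_hz <- (seq_len(seg_n) - 1) / seg_n * fs
  half <- 2:(seg_n %/% 2L) # one-sided, excluding DC
  freq_cpm <- freqs_hz[half] * 60
  psd <- 2 * psd[half]
  band <- freq_cpm >= sc$psd_fit_band_cpm[1] - 1e-12 &
    freq_cpm <= sc$psd_fit_band_cpm[2] + 1e-12 & psd > 0
  if (sum(band) < 2L)
    stop("no positive PSD values in the aperiodic fit band")
  fit <- stats::lm(log10(psd[band]) ~ log10(freq_cpm[band]))
  list(kappa = -unname(stats::coef(fit)[2]),
       freq_cpm = freq_cpm[band], psd = psd[band])
}

#' One-row data frame of photometry metrics
#'
#' @param fp A `photometry_trace`.
#' @param bg_peak_time_s Time of peak blood glucose in seconds (`NA`
#'   allowed; the clipped AUC is then reported as `NA`).
#' @param config Configuration list.
#' @param seed Seed for the spectral-onset pseudo-onset draw.
#' @return A one-row `data.frame` of per-session photometry metrics.
#' @export
photometry_metrics_row <- function(fp, bg_peak_time_s = NA_real_,
                                   config = default_config(), seed = 1L) {
  pc <- config$photometry
  pk <- peak_z_response(fp, pc$peak_window_s, direction = "inhibition")
  neg <- if (is.na(bg_peak_time_s)) NA_real_ else
    negative_auc(fp, bg_peak_time_s)
  so <- tryCatch(band_power_onset(fp, config, seed = seed)$onset_s,
                 error = function(e) NA_real_)
  kappa <- tryCatch(
    psd_aperiodic_slope(fp, pc$baseline_window_s, config)$kappa,
    error = function(e) NA_real_)
  data.frame(
    fp_peak_z = pk$value, fp_peak_z_time_s = pk$time_s,
    fp_neg_auc_z_min = neg,
    fp_total_auc_z_min = total_auc(fp),
    fp_psd_kappa = kappa,
    fp_spectral_onset_s = so)
}
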