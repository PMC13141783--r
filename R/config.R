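# Central run configuration: every tunable used anywhere in the pipeline,
# with the defaults used for recorded data. Serializes losslessly to JSON.

#' Default pipeline configuration
#'
#' Returns the full nested list of tunables with their standard defaults:
#'
#' * `glucose`: despike `k` (2), median window (7 samples), causal
#'   smoothing window (60 samples), baseline window (-25..0 min), onset
#'   local-baseline window (-5..0 min), onset boxcar (120 samples = 2
#'   min), onset threshold multiplier `z` (3), sustain (60 s), post
#'   window (0..90 min), early derivative window (0..30 min), plateau
#'   band fraction (0.1) and sustain (120 s).
#' * `photometry`: the same robust chain plus the zero-phase Butterworth
#'   low-pass (4-min period, order 3) and the peak-z window (0..15 min;
#'   0..10 min is the alternative convention, set `peak_window_s`).
#' * `spectral`: slow band (1/20..1/14 cycles/min), spectrogram window
#'   (20 min) and overlap (0.99), null count (200), guard (5 min),
#'   detection window (-10..+10 min), alpha (0.05), aperiodic PSD fit
#'   band (0.05..0.5 cycles/min).
#' * `early_model`: model window (-25..+1 min), lag grid (-1..+1 min in
#'   0.25-min steps), fold count (5), training doses ({1, 2, 2.5} g/kg).
#' * `coupling`: maximum lag (20 min), minimum overlap (120 samples),
#'   analysis window (-25..90 min, the full session, so that the
#'   anticipatory descent participates; for residual traces the window
#'   starts at +3 min, beyond the reach of the fitted early pattern:
#'   model window end +1 min, maximum template lag +1 min, plus the
#'   low-pass settling half-width +1 min — calibrated on synthetic
#'   cohorts with known coupling lag), null pairings per session (100),
#'   minimum circular offset (20 min), BH alpha (0.01), analysis dose
#'   (2 g/kg), group-delay compensation flag.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    glucose = list(
      despike_k = 2.0,
      despike_local_window = 7L,
      median_window = 7L,
      smooth_window = 60L,
      baseline_window_s = c(-1500, 0),
      onset_baseline_window_s = c(-300, 0),
      onset_boxcar_window = 120L,
      onset_z = 3,
      onset_sustain_s = 60,
      post_window_s = c(0, 5400),
      early_deriv_window_s = c(0, 1800),
      plateau_band_frac = 0.1,
      plateau_sustain_s = 120),
    photometry = list(
      despike_k = 2.0,
      despike_local_window = 7L,
      median_window = 7L,
      smooth_window = 60L,
      lowpass_period_min = 4,
      lowpass_order = 3L,
      baseline_window_s = c(-1500, 0),
      peak_window_s = c(0, 900)),
    spectral = list(
      band_cpm = c(1 / 20, 1 / 14),
      window_min = 20,
      overlap = 0.99,
      n_null = 200L,
      guard_min = 5,
      detect_window_s = c(-600, 600),
      alpha = 0.05,
      psd_fit_band_cpm = c(0.05, 0.5)),
    early_model = list(
      window_s = c(-1500, 60),
      tau_grid_min = seq(-1, 1, by = 0.25),
      k_folds = 5L,
      training_doses = c(1, 2, 2.5),
      residual_windows_min = list(c(0, 10), c(10, 60))),
    coupling = list(
      max_lag_s = 1200,
      min_overlap = 120L,
      window_s = c(-1500, 5400),
      residual_window_s = c(180, 5400),
      n_pairings = 100L,
      min_offset_s = 1200,
      alpha = 0.01,
      analysis_dose = 2,
      compensate_delay = TRUE))
}

#' Serialize / restore a configuration
#'
#' @param config A configuration list.
#' @param path File path for the JSON round trip.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # Restore types that JSON flattens.
  cfg$glucose$median_window <- as.integer(cfg$glucose$median_window)
  cfg$glucose$smooth_window <- as.integer(cfg$glucose$smooth_window)
  cfg$glucose$onset_boxcar_window <- as.integer(cfg$glucose$onset_boxcar_window)
  cfg$photometry$median_window <- as.integer(cfg$photometry$median_window)
  cfg$photometry$smooth_window <- as.integer(cfg$photometry$smooth_window)
  cfg$photometry$lowpass_order <- as.integer(cfg$photometry$lowpass_order)
  cfg$spectral$n_null <- as.integer(cfg$spectral$n_null)
  cfg$early_model$k_folds <- as.integer(cfg$early_model$k_folds)
  cfg$early_model$residual_windows_min <-
    lapply(seq_len(nrow(cfg$early_model$residual_windows_min)),
           function(i) as.numeric(cfg$early_model$residual_windows_min[i, ]))
  cfg$coupling$min_overlap <- as.integer(cfg$coupling$min_overlap)
  cfg$coupling$n_pairings <- as.integer(cfg$coupling$n_pairings)
  cfg
}
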