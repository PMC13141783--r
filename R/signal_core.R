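# Robust signal-processing primitives shared by the glucose and photometry
# streams. All operate on `uniform_trace` objects and return new traces;
# causal operations record their group delay in the trace metadata.

robust_mad_scale <- function(x) {
  1.4826 * stats::median(abs(x - stats::median(x)))
}

#' Robust MAD despiking
#'
#' Flags samples whose absolute deviation from the trace median exceeds
#' `k` times the median absolute deviation (MAD) and replaces them by
#' linear interpolation between the nearest unflagged neighbours; flagged
#' samples at the boundaries take the nearest unflagged value. When the MAD
#' is zero (at least half the samples equal the median) the threshold is
#' treated as infinite except for samples that differ from the median by
#' more than a small absolute guard (`1e-9 * |median| + 1e-12`), which are
#' still flagged; this avoids flagging entire near-constant traces.
#'
#' @param trace A NA-free `uniform_trace`.
#' @param k Positive threshold multiplier (2.0 for recorded data).
#' @param local_window Optional odd window length. When given, deviations
#'   are measured from a centered running median of that window instead of
#'   the global median, so slow physiological structure (a glycemic
#'   excursion, a sustained inhibition) is not mistaken for spikes; the
#'   MAD of those deviations still sets the threshold globally. The
#'   preprocessing chains use `local_window = 7`.
#' @return A `uniform_trace` with flagged samples replaced; all other
#'   samples are bit-identical to the input.
#' @export
despike_mad <- function(trace, k = 2.0, local_window = NULL) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (!is.finite(k) || k <= 0) stop("k must be a positive real")
  if (anyNA(trace$values)) stop("despike_mad requires a NaN/NA-free trace")
  y <- trace$values
  if (is.null(local_window)) {
    ref <- rep(stats::median(y), length(y))
  } else {
    local_window <- as.integer(local_window)
    if (local_window < 1L || local_window %% 2L == 0L)
      stop("local_window must be an odd integer >= 1")
    w <- min(local_window, length(y))
    if (w %% 2L == 0L) w <- w - 1L
    ref <- as.numeric(stats::runmed(y, k = w, endrule = "med"))
  }
  resid <- y - ref
  med <- stats::median(resid)
  mad_s <- stats::median(abs(resid - med))
  dev <- abs(resid - med)
  if (mad_s > 0) {
    flagged <- dev > k * mad_s
  } else {
    flagged <- dev > (1e-9 * abs(med) + 1e-12)
  }
  if (all(flagged))
    stop("despike_mad: all samples flagged (degenerate trace starting at t0 = ",
         trace$t0, " s)")
  if (!any(flagged)) return(trace)
  y[flagged] <- NA_real_
  y <- interpolate_flagged(y)
  trace_with(trace, y)
}

# Linear interpolation across NA runs; boundary NAs take the nearest
# non-NA value.
interpolate_flagged <- function(y) {
  idx <- which(!is.na(y))
  stats::approx(x = idx, y = y[idx], xout = seq_along(y), rule = 2)$y
}

#' Centered median filter
#'
#' Each output sample is the median over a centered window of odd length;
#' near the edges the window shrinks symmetrically to fit inside the trace
#' (so the first and last samples pass through unchanged for any window).
#'
#' @param trace A `uniform_trace`.
#' @param window Odd window length in samples (>= 1).
#' @return The filtered `uniform_trace` (no group delay).
#' @export
median_filter_centered <- function(trace, window = 7L) {
  stopifnot(inherits(trace, "uniform_trace"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1")
  n <- length(trace$values)
  if (window > n) stop("median filter window (", window,
                       ") larger than trace (", n, " samples)")
  if (window == 1L) return(trace)
  y <- trace$values
  out <- as.numeric(stats::runmed(y, k = window, endrule = "keep"))
  # Edges: shrink the window symmetrically so it stays fully inside.
  h <- (window - 1L) %/% 2L
  for (i in seq_len(h)) {
    hh <- i - 1L
    out[i] <- stats::median(y[seq_len(2L * hh + 1L)])
    out[n - i + 1L] <- stats::median(y[(n - 2L * hh):n])
  }
  trace_with(trace, out)
}

#' Causal moving average
#'
#' `output[i] = mean(input[max(1, i - window + 1) .. i])`: strictly causal,
#' so no output sample depends on later input (responses stay aligned in
#' time, at the cost of a group delay of `(window - 1) / 2` samples which
#' is recorded in the trace metadata).
#'
#' @param trace A `uniform_trace`.
#' @param window Window length in samples (>= 1).
#' @return The smoothed `uniform_trace`.
#' @export
causal_moving_average <- function(trace, window = 60L) {
  stopifnot(inherits(trace, "uniform_trace"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window == 1L) return(trace)
  y <- trace$values
  n <- length(y)
  cs <- cumsum(y)
  out <- numeric(n)
  head_n <- seq_len(min(window, n))
  out[head_n] <- cs[head_n] / head_n
  if (n > window)
    out[(window + 1):n] <- (cs[(window + 1):n] - cs[1:(n - window)]) / window
  trace_with(trace, out, extra_delay_s = (window - 1) / 2 / trace$fs)
}

#' Smoothed finite-difference derivative
#'
#' First differences at the native sample spacing (units per second), with
#' the leading sample padded with 0, then smoothed with a causal moving
#' average of `smooth_window` samples.
#'
#' @param trace A `uniform_trace` (length >= 2).
#' @param smooth_window Causal smoothing window in samples (>= 1).
#' @return A `uniform_trace` of the derivative in units per second.
#' @export
finite_difference_derivative <- function(trace, smooth_window = 60L) {
  stopifnot(inherits(trace, "uniform_trace"))
  y <- trace$values
  d <- c(0, diff(y)) * trace$fs
  # A backward difference refers to the midpoint of its two samples, so the
  # stored sample lags its physical content by half a sample.
  out <- trace_with(trace, d, extra_delay_s = 0.5 / trace$fs)
  causal_moving_average(out, smooth_window)
}

#' Subtract a robust baseline
#'
#' Subtracts the median of the trace over the baseline window (the
#' pre-event period, -25 to 0 min for recorded data), yielding an excursion
#' relative to baseline. The baseline value is attached as attribute
#' `baseline_value`.
#'
#' @param trace A `uniform_trace`.
#' @param baseline_window Numeric `c(t_start, t_end)` in seconds.
#' @return The baseline-subtracted `uniform_trace`.
#' @export
baseline_subtract <- function(trace, baseline_window = c(-1500, 0)) {
  stopifnot(inherits(trace, "uniform_trace"))
  idx <- window_indices(trace, baseline_window[1], baseline_window[2])
  if (length(idx) == 0L)
    stop(sprintf("baseline window [%g, %g] s does not overlap the trace",
                 baseline_window[1], baseline_window[2]))
  b <- stats::median(trace$values[idx])
  out <- trace_with(trace, trace$values - b)
  attr(out, "baseline_value") <- b
  out
}

#' Baseline z-score
#'
#' Centers and scales a trace by the mean and SD of its baseline window,
#' so the output has mean 0 and SD 1 over the baseline.
#'
#' @param trace A `uniform_trace`.
#' @param baseline_window Numeric `c(t_start, t_end)` in seconds.
#' @param label Identifier used in error messages (e.g. a session ID).
#' @return The z-scored `uniform_trace`.
#' @export
zscore_baseline <- function(trace, baseline_window = c(-1500, 0),
                            label = "trace") {
  stopifnot(inherits(trace, "uniform_trace"))
  idx <- window_indices(trace, baseline_window[1], baseline_window[2])
  if (length(idx) < 2L)
    stop("baseline window overlaps fewer than 2 samples")
  m <- mean(trace$values[idx])
  s <- stats::sd(trace$values[idx])
  if (!is.finite(s) || s <= 0)
    stop("zscore_baseline: zero baseline SD in ", label)
  trace_with(trace, (trace$values - m) / s)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter with cutoff frequency
#' `1 / cutoff_period` and applies it forward and backward
#' (`signal::filtfilt`), giving zero phase shift; the effective amplitude
#' response is the square of the single-pass Butterworth magnitude.
#'
#' @param trace A `uniform_trace`.
#' @param cutoff_period_min Cutoff period in minutes (4 for recorded data).
#' @param order Filter order (3 for recorded data).
#' @return The filtered `uniform_trace` (no group delay).
#' @export
lowpass_zero_phase <- function(trace, cutoff_period_min = 4, order = 3L) {
  stopifnot(inherits(trace, "uniform_trace"))
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  cutoff_s <- cutoff_period_min * 60
  if (cutoff_s <= 2 / trace$fs)
    stop("cutoff period must exceed twice the sample spacing")
  n <- length(trace$values)
  # the two passes need runway for their edge handling: require several
  # filter lengths of data.
  if (n <= 12L * (order + 1L))
    stop("trace too short (", n, " samples) for zero-phase filtering at order ",
         order)
  w <- 2 * (1 / cutoff_s) / trace$fs
  bf <- signal::butter(order, w, type = "low")
  # Odd-reflection padding of ~6 cutoff periods on both ends: the
  # zero-state transients of the forward and backward passes then settle
  # inside the padding instead of corrupting the trace edges.
  y <- trace$values
  pad <- min(n - 1L, 6L * as.integer(round(cutoff_s * trace$fs)))
  front <- 2 * y[1] - y[(pad + 1L):2L]
  back <- 2 * y[n] - y[(n - 1L):(n - pad)]
  yy <- c(front, y, back)
  fwd <- as.numeric(signal::filter(bf, yy))
  bwd <- rev(as.numeric(signal::filter(bf, rev(fwd))))
  trace_with(trace, bwd[(pad + 1L):(pad + n)])
}

#' Regress out a reference channel
#'
#' Least-squares fit `signal ~ a * reference + b` and subtraction of the
#' fitted component; removes motion and photobleaching artifacts shared
#' with the isosbestic reference. The output has zero sample correlation
#' with the reference. A constant reference degenerates to an
#' intercept-only fit (mean subtraction).
#'
#' @param sig Signal channel, a `uniform_trace`.
#' @param reference Reference channel, a `uniform_trace` with the same
#'   length and alignment.
#' @return The corrected `uniform_trace`; fit coefficients attached as
#'   attribute `fit` (named vector `a`, `b`).
#' @export
regress_out_reference <- function(sig, reference) {
  stopifnot(inherits(sig, "uniform_trace"),
            inherits(reference, "uniform_trace"))
  if (length(sig$values) != length(reference$values) ||
      abs(sig$t0 - reference$t0) > 1e-9)
    stop("signal and reference must have equal length and alignment")
  x <- reference$values
  y <- sig$values
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) {
    a <- 0
    b <- mean(y)
  } else {
    a <- stats::cov(x, y) / vx
    b <- mean(y) - a * mean(x)
  }
  out <- trace_with(sig, y - (a * x + b))
  attr(out, "fit") <- c(a = a, b = b)
  out
}
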