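# Uniformly sampled scalar time series, event-aligned (t = 0 at gavage).

#' Construct a uniformly sampled trace
#'
#' A `uniform_trace` is the basic container used throughout the package: a
#' real-valued series sampled at a fixed rate (1 Hz for all recorded data)
#' on a time axis expressed in seconds relative to the gavage (t = 0).
#'
#' @param values Numeric vector of samples (length >= 2).
#' @param t0 Time of the first sample in seconds relative to the event.
#' @param fs Sampling rate in Hz (default 1).
#' @param group_delay_s Accumulated group delay (seconds) introduced by
#'   causal filtering applied to this trace; carried as metadata so that
#'   timing analyses can compensate it. Default 0.
#' @param allow_na Permit NA values (used transiently between despiking and
#'   interpolation); exported traces are NA-free.
#' @return An object of class `uniform_trace`.
#' @export
uniform_trace <- function(values, t0 = 0, fs = 1, group_delay_s = 0,
                          allow_na = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("uniform_trace requires at least 2 samples, got ", length(values))
  if (!allow_na && anyNA(values))
    stop("uniform_trace contains NA values; exported traces must be NA-free")
  if (!is.finite(t0)) stop("t0 must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  structure(
    list(values = values, t0 = as.numeric(t0), fs = as.numeric(fs),
         group_delay_s = as.numeric(group_delay_s)),
    class = "uniform_trace")
}

#' Time axis of a trace
#'
#' @param trace A `uniform_trace`.
#' @return Numeric vector of sample times in seconds relative to the event.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' @export
print.uniform_trace <- function(x, ...) {
  tt <- trace_times(x)
  cat(sprintf(
    "<uniform_trace> %d samples @ %g Hz, t = [%.1f, %.1f] s, delay %.1f s\n",
    length(x$values), x$fs, tt[1], tt[length(tt)], x$group_delay_s))
  invisible(x)
}

#' @export
as.data.frame.uniform_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$values)
}

#' @export
length.uniform_trace <- function(x) length(x$values)

# Indices of samples with time in [t_start, t_end] (seconds, closed).
window_indices <- function(trace, t_start, t_end) {
  tt <- trace_times(trace)
  which(tt >= t_start - 1e-9 & tt <= t_end + 1e-9)
}

#' Extract a time window of a trace
#'
#' @param trace A `uniform_trace`.
#' @param t_start,t_end Window bounds in seconds (closed interval).
#' @return A `uniform_trace` restricted to the window.
#' @export
trace_slice <- function(trace, t_start, t_end) {
  idx <- window_indices(trace, t_start, t_end)
  if (length(idx) < 2L)
    stop(sprintf("window [%g, %g] s overlaps fewer than 2 samples",
                 t_start, t_end))
  uniform_trace(trace$values[idx], t0 = trace_times(trace)[idx[1]],
                fs = trace$fs, group_delay_s = trace$group_delay_s)
}

# Replace the values of a trace, preserving axis metadata.
trace_with <- function(trace, values, extra_delay_s = 0, allow_na = FALSE) {
  uniform_trace(values, t0 = trace$t0, fs = trace$fs,
                group_delay_s = trace$group_delay_s + extra_delay_s,
                allow_na = allow_na)
}

#' Compensate accumulated causal-filter group delay
#'
#' Causal moving averages and finite differences delay a trace by a known
#' number of samples. For timing-sensitive analyses (notably lagged
#' cross-correlation) this helper advances the trace by the rounded
#' accumulated delay, dropping the leading samples, so that two traces
#' processed through different causal chains can be compared on a common
#' physical time axis.
#'
#' @param trace A `uniform_trace` whose `group_delay_s` is to be removed.
#' @return A `uniform_trace` with `group_delay_s` 0 and adjusted `t0`.
#' @export
compensate_delay <- function(trace) {
  d <- round(trace$group_delay_s * trace$fs)
  if (d <= 0) {
    trace$group_delay_s <- 0
    return(trace)
  }
  n <- length(trace$values)
  if (d >= n - 1) stop("group delay exceeds trace length")
  uniform_trace(trace$values[(d + 1):n], t0 = trace$t0, fs = trace$fs,
                group_delay_s = 0)
}
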