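# Brute-force reference implementations and small constructors shared by
# the test files. The oracles deliberately use plain loops and base
# functions, independent of the package's vectorized/FFT code paths.

make_trace <- function(values, t0 = 0) uniform_trace(values, t0 = t0)

# Wrap a z trace as a photometry_trace (for metric functions that take
# the preprocessed object).
make_fp <- function(z_trace) {
  structure(list(z = z_trace, corrected = z_trace, degenerate = FALSE),
            class = "photometry_trace")
}

# Ornstein-Uhlenbeck noise at 1 Hz.
ou_noise <- function(n, sd = 0.3, tau_s = 300) {
  a <- exp(-1 / tau_s)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n, 0, sd * sqrt(1 - a^2))
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i]
  x
}

# Direct per-sample evaluation of the global-median MAD despike rule.
brute_despike_flags <- function(y, k) {
  med <- median(y)
  mad_s <- median(abs(y - med))
  if (mad_s > 0) abs(y - med) > k * mad_s
  else abs(y - med) > (1e-9 * abs(med) + 1e-12)
}

# Explicit sliding median with symmetric shrinking edges.
brute_median_filter <- function(y, w) {
  h <- (w - 1) / 2
  n <- length(y)
  sapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    median(y[(i - hh):(i + hh)])
  })
}

brute_causal_ma <- function(y, w) {
  sapply(seq_along(y), function(i) mean(y[max(1, i - w + 1):i]))
}

# Trapezoid integral by explicit summation (x in minutes).
brute_trapz <- function(x, y) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1]) * (y[i] + y[i - 1]) / 2
  s
}

# Lagged Spearman by plain loops: global ranks, cor() per lag.
brute_lagged_spearman <- function(x, y, lags) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  sapply(lags, function(L) {
    if (L >= 0) suppressWarnings(cor(rx[(1 + L):n], ry[1:(n - L)]))
    else suppressWarnings(cor(rx[1:(n + L)], ry[(1 - L):n]))
  })
}

# Glucose trace object built directly from a clean excursion (bypasses
# the robust chain; used to test excursion_summary geometry in isolation).
synthetic_glucose_trace <- function(delta, t0 = -1500, config = default_config()) {
  gc <- config$glucose
  tr <- uniform_trace(delta, t0 = t0)
  y0 <- baseline_subtract(tr, gc$onset_baseline_window_s)
  y0s <- causal_moving_average(y0, gc$onset_boxcar_window)
  deriv <- finite_difference_derivative(y0s, gc$smooth_window)
  structure(
    list(raw = tr, clean = tr, delta_g = tr, raw_delta = tr,
         level_onset = y0, level_onset_smooth = y0s, derivative = deriv,
         baseline_value = 0),
    class = "glucose_trace")
}

# Single-pass Butterworth magnitude response (low-pass, analog prototype);
# the zero-phase filter applies it twice.
butter_gain <- function(f, fc, order) 1 / sqrt(1 + (f / fc)^(2 * order))

# A smooth early-response template shape on the model-window grid:
# flat baseline, cosine descent over [-4, -0.5] min, plateau at -2.5.
reference_template <- function(window = c(-1500, 60)) {
  grid <- seq(window[1], window[2], by = 1)
  v <- ifelse(grid < -240, 0,
       ifelse(grid < -30, -2.5 * (1 - cos(pi * (grid + 240) / 210)) / 2, -2.5))
  structure(list(values = v, time_s = grid, window = window,
                 n_sessions = 10L),
            class = "early_template")
}
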