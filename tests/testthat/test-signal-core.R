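# Robust signal-processing primitives against brute-force oracles and
# analytic expectations.

test_that("MAD despiking preserves constants and removes isolated spikes", {
  expect_equal(despike_mad(make_trace(rep(5, 5)), k = 2)$values, rep(5, 5))
  expect_equal(despike_mad(make_trace(c(0, 0, 0, 100, 0, 0, 0)), k = 2)$values,
               rep(0, 7))
  # boundary spike takes the nearest unflagged value
  expect_equal(despike_mad(make_trace(c(100, 0, 0, 0, 0, 0, 0)), k = 2)$values,
               rep(0, 7))
  expect_error(despike_mad(make_trace(c(1, 2)), k = -1), "positive")
})

test_that("despike flag set matches per-sample brute-force rule", {
  set.seed(101)
  y <- rnorm(600)
  spikes <- sample(600, 10)
  y[spikes] <- y[spikes] + 20 * sample(c(-1, 1), 10, replace = TRUE)
  out <- despike_mad(make_trace(y), k = 2)
  flags <- brute_despike_flags(y, 2)
  expect_true(all(spikes %in% which(flags)))
  # unflagged samples bit-identical, flagged samples changed
  expect_identical(out$values[!flags], y[!flags])
  expect_false(any(out$values[spikes] == y[spikes]))
})

test_that("local-window despiking spares slow structure", {
  set.seed(7)
  ramp <- seq(0, 100, length.out = 500) + rnorm(500, 0, 0.5)
  spiked <- ramp; spiked[250] <- spiked[250] + 50
  out <- despike_mad(make_trace(spiked), k = 2, local_window = 7)
  expect_lt(abs(out$values[250] - ramp[250]), 3)
  expect_lt(max(abs(out$values - ramp)), 5) # excursion-scale structure kept
})

test_that("centered median filter matches brute-force sliding median", {
  expect_equal(median_filter_centered(make_trace(c(3, 1, 4)), 1)$values,
               c(3, 1, 4))
  expect_equal(median_filter_centered(make_trace(c(1, 9, 1, 1, 1)), 3)$values,
               c(1, 1, 1, 1, 1))
  set.seed(11)
  y <- rnorm(100)
  expect_equal(median_filter_centered(make_trace(y), 7)$values,
               brute_median_filter(y, 7))
  expect_error(median_filter_centered(make_trace(rnorm(5)), 7), "larger")
  expect_error(median_filter_centered(make_trace(y), 4), "odd")
})

test_that("causal moving average is exact, causal, and variance-reducing", {
  expect_equal(causal_moving_average(make_trace(rep(2, 50)), 10)$values,
               rep(2, 50))
  # unit step: linear ramp over the window
  y <- c(rep(0, 100), rep(1, 100))
  out <- causal_moving_average(make_trace(y), 60)$values
  expect_equal(out[101:160], (1:60) / 60)
  expect_equal(out[170], 1)
  set.seed(12)
  y <- rnorm(200)
  expect_equal(causal_moving_average(make_trace(y), 13)$values,
               brute_causal_ma(y, 13))
  # causality: truncating the input never changes earlier outputs
  full <- causal_moving_average(make_trace(y), 13)$values
  part <- causal_moving_average(make_trace(y[1:120]), 13)$values
  expect_identical(full[1:120], part)
  # white-noise variance reduced by ~ the window length
  set.seed(13)
  w <- rnorm(10000)
  v <- var(causal_moving_average(make_trace(w), 25)$values[25:10000])
  expect_lt(abs(v - 1 / 25) / (1 / 25), 0.2)
})

test_that("smoothed derivative recovers slopes and sine amplitude", {
  ramp <- make_trace(0.5 * (0:499))
  d <- finite_difference_derivative(ramp, 60)$values
  expect_equal(d[100:499], rep(0.5, 400), tolerance = 1e-12)
  expect_equal(finite_difference_derivative(make_trace(rep(3, 100)), 60)$values,
               rep(0, 100))
  # sine of period 20 min: derivative amplitude 2*pi/1200 x amplitude,
  # attenuated by the 60-sample boxcar (sinc factor)
  tt <- 0:11999
  s <- make_trace(10 * sin(2 * pi * tt / 1200))
  d <- finite_difference_derivative(s, 60)$values[2000:10000]
  expected <- 10 * 2 * pi / 1200
  atten <- abs(sin(pi * 60 / 1200) / (60 * sin(pi / 1200)))
  expect_equal(max(d), expected * atten, tolerance = 0.02)
  # causality
  y <- rnorm(300)
  full <- finite_difference_derivative(make_trace(y), 60)$values
  part <- finite_difference_derivative(make_trace(y[1:200]), 60)$values
  expect_identical(full[1:200], part)
})

test_that("baseline subtraction uses the window median and is idempotent", {
  tr <- make_trace(c(rep(120, 100), rep(180, 100)), t0 = -100)
  out <- baseline_subtract(tr, c(-100, -1))
  expect_equal(attr(out, "baseline_value"), 120)
  expect_equal(out$values, c(rep(0, 100), rep(60, 100)))
  twice <- baseline_subtract(out, c(-100, -1))
  expect_equal(twice$values, out$values)
  expect_error(baseline_subtract(tr, c(500, 600)), "overlap")
})

test_that("baseline z-score normalizes the window and is affine-invariant", {
  set.seed(14)
  y <- rnorm(400, 5, 2)
  tr <- make_trace(y, t0 = -200)
  z <- zscore_baseline(tr, c(-200, 0))
  idx <- 1:201
  expect_equal(mean(z$values[idx]), 0, tolerance = 1e-12)
  expect_equal(sd(z$values[idx]), 1, tolerance = 1e-12)
  z2 <- zscore_baseline(make_trace(3 * y - 7, t0 = -200), c(-200, 0))
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  # hand-computed 5-sample baseline
  tr5 <- make_trace(c(1, 2, 3, 4, 5, 10), t0 = -4)
  z5 <- zscore_baseline(tr5, c(-4, 0))
  expect_equal(z5$values, (c(1, 2, 3, 4, 5, 10) - 3) / sd(1:5))
  expect_error(zscore_baseline(make_trace(rep(1, 50), t0 = -25), c(-25, 0),
                               label = "S1"), "S1")
})

test_that("zero-phase low-pass matches the squared Butterworth response", {
  fc <- 1 / 240 # 4-min cutoff
  dc <- lowpass_zero_phase(make_trace(rep(4, 2000)), 4, 3)
  expect_equal(dc$values[100:1900], rep(4, 1801), tolerance = 1e-6)
  tt <- 0:5999
  # 30-s period: far above cutoff, two-pass gain ~ 1e-11
  fast <- lowpass_zero_phase(make_trace(sin(2 * pi * tt / 30)), 4, 3)
  expect_lt(max(abs(fast$values[1000:5000])), 0.05)
  # 20-min period: amplitude within 2%, phase shift < 1 sample
  slow_in <- sin(2 * pi * tt / 1200)
  slow <- lowpass_zero_phase(make_trace(slow_in), 4, 3)
  seg <- 1500:4500
  amp <- max(slow$values[seg])
  g2 <- butter_gain(1 / 1200, fc, 3)^2
  expect_equal(amp, g2, tolerance = 0.02)
  shift <- which.max(ccf(slow$values[seg], slow_in[seg], lag.max = 5,
                         plot = FALSE)$acf) - 6
  expect_lte(abs(shift), 1)
  expect_error(lowpass_zero_phase(make_trace(rnorm(10)), 4, 3), "short")
})

test_that("reference regression removes the fitted component exactly", {
  set.seed(15)
  ref <- make_trace(rnorm(500))
  sig <- make_trace(2 * ref$values + 3)
  out <- regress_out_reference(sig, ref)
  expect_equal(out$values, rep(0, 500), tolerance = 1e-12)
  # output orthogonal to reference
  sig2 <- make_trace(rnorm(500) + 0.5 * ref$values)
  out2 <- regress_out_reference(sig2, ref)
  expect_equal(cor(out2$values, ref$values), 0, tolerance = 1e-10)
  # uncorrelated reference: a ~ 0, output ~ signal - mean
  indep <- make_trace(rnorm(500, 10))
  out3 <- regress_out_reference(indep, ref)
  expect_lt(abs(attr(out3, "fit")[["a"]]), 0.1)
  expect_lt(max(abs(out3$values - (indep$values - mean(indep$values)))), 0.3)
  # constant reference: intercept-only fallback
  out4 <- regress_out_reference(indep, make_trace(rep(1, 500)))
  expect_equal(out4$values, indep$values - mean(indep$values))
})

test_that("reference regression recovers the neural component (r > 0.95)", {
  set.seed(16)
  n <- 5000
  neural <- 2 * sin(2 * pi * (1:n) / 900) + ou_noise(n, 0.5, 120)
  artifact <- 5 * ou_noise(n, 1, 30)
  sig <- make_trace(neural + artifact)
  ref <- make_trace(0.8 * artifact)
  out <- regress_out_reference(sig, ref)
  expect_gt(cor(out$values, neural), 0.95)
})

test_that("group delays accumulate and are compensated by integer shift", {
  tr <- make_trace(rnorm(300))
  ma <- causal_moving_average(tr, 61)
  expect_equal(ma$group_delay_s, 30)
  comp <- compensate_delay(ma)
  expect_equal(comp$group_delay_s, 0)
  expect_equal(comp$values, ma$values[31:300])
  expect_equal(comp$t0, tr$t0)
})
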