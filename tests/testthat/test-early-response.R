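# Template construction, lagged template regression, cross-validated lag
# selection, leakage guard, and residual decomposition.

cfg <- default_config()
em <- cfg$early_model

session_from_template <- function(template, beta0, beta1, tau_min, noise_sd,
                                  span = c(-1500, 5400)) {
  tt <- seq(span[1], span[2], by = 1)
  v <- beta0 + beta1 * glycophot:::shift_template(template, tt, tau_min * 60) +
    rnorm(length(tt), 0, noise_sd)
  uniform_trace(v, t0 = span[1])
}

test_that("the template is the pointwise median and resists outliers", {
  tmpl0 <- reference_template()
  set.seed(41)
  z1 <- session_from_template(tmpl0, 0, 1, 0, 0)
  expect_equal(build_template(list(z1, z1, z1), em$window_s)$values,
               tmpl0$values)
  # one extreme outlier leaves the median template unchanged
  z_out <- trace_with(z1, z1$values * 50 + 100)
  tm <- build_template(list(z1, z1, z_out), em$window_s)
  expect_equal(tm$values, tmpl0$values)
  # sessions lacking coverage are excluded with a warning
  short <- uniform_trace(rnorm(3000), t0 = 0)
  expect_warning(build_template(list(z1, z1, short), em$window_s), "excluded")
  expect_error(suppressWarnings(build_template(list(short, short),
                                               em$window_s)), "cover")
})

test_that("template averaging reduces noise like a median of n", {
  tmpl0 <- reference_template()
  set.seed(42)
  zl <- lapply(1:5, function(i) session_from_template(tmpl0, 0, 1, 0, 0.3))
  tm <- build_template(zl, em$window_s)
  rmse <- sqrt(mean((tm$values - tmpl0$values)^2))
  expect_lt(rmse, 0.3 / sqrt(5) * 2)
})

test_that("session fits recover exact affine relations to the template", {
  tmpl0 <- reference_template()
  z <- session_from_template(tmpl0, 0, 1, 0, 0)
  f <- fit_session(z, tmpl0, 0)
  expect_equal(f$beta0, 0, tolerance = 1e-10)
  expect_equal(f$beta1, 1, tolerance = 1e-10)
  expect_lt(f$mse, 1e-20)
  z2 <- session_from_template(tmpl0, -0.5, 2, 0, 0)
  f2 <- fit_session(z2, tmpl0, 0)
  expect_equal(f2$beta0, -0.5, tolerance = 1e-10)
  expect_equal(f2$beta1, 2, tolerance = 1e-10)
  flat <- structure(list(values = rep(1, 1561),
                         time_s = seq(-1500, 60), window = c(-1500, 60),
                         n_sessions = 2L), class = "early_template")
  expect_error(fit_session(z, flat, 0), "degenerate")
})

test_that("grid search localizes a known template shift", {
  tmpl0 <- reference_template()
  set.seed(43)
  hits <- 0
  for (i in 1:20) {
    z <- session_from_template(tmpl0, 0, 1, 0.5, 0.05)
    mses <- sapply(em$tau_grid_min, function(tau)
      fit_session(z, tmpl0, tau)$mse)
    if (em$tau_grid_min[which.min(mses)] == 0.5) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("cross-validated lag selection is consistent and breaks ties", {
  tmpl0 <- reference_template()
  set.seed(44)
  zl <- lapply(1:10, function(i) session_from_template(tmpl0, 0, 1, 0, 0.1))
  subj <- rep(sprintf("S%d", 1:5), each = 2)
  sel <- select_lag_cv(zl, subj, cfg)
  # a commonly shifted cohort has relative lag 0 by construction: the
  # rebuilt template inherits any common shift
  expect_equal(sel$tau_min, 0)
  zl_s <- lapply(1:10, function(i) session_from_template(tmpl0, 0, 1, -0.75, 0.1))
  sel_s <- select_lag_cv(zl_s, subj, cfg)
  expect_equal(sel_s$tau_min, 0)
  expect_equal(nrow(sel$cv), length(em$tau_grid_min))
  # exact MSE ties resolve to higher R2 then smaller |tau|
  cvt <- data.frame(tau_min = c(-0.5, 0.25, 0.5), mse = c(1, 1, 1),
                    r2 = c(0.9, 0.9, 0.95))
  ord <- order(cvt$mse, -cvt$r2, abs(cvt$tau_min), cvt$tau_min)
  expect_equal(cvt$tau_min[ord[1]], 0.5)
  # single subject: plain K-fold with a warning
  expect_warning(select_lag_cv(zl[1:4], rep("S1", 4), cfg), "single subject")
})

test_that("no sample after the model window influences the fit (leakage guard)", {
  tmpl0 <- reference_template()
  set.seed(45)
  zl <- lapply(1:6, function(i) session_from_template(tmpl0, 0, 1, 0, 0.1))
  subj <- rep(sprintf("S%d", 1:3), each = 2)
  mutate_post <- function(z) {
    tt <- trace_times(z)
    v <- z$values
    v[tt > 60] <- v[tt > 60] + 100 * rnorm(sum(tt > 60))
    trace_with(z, v)
  }
  zl_mut <- lapply(zl, mutate_post)
  sel1 <- select_lag_cv(zl, subj, cfg)
  sel2 <- select_lag_cv(zl_mut, subj, cfg)
  expect_identical(sel1$tau_min, sel2$tau_min)
  expect_identical(sel1$cv, sel2$cv)
  t1 <- build_template(zl, em$window_s)
  t2 <- build_template(zl_mut, em$window_s)
  expect_identical(t1$values, t2$values)
  f1 <- predict_and_residual(zl[[1]], t1, sel1$tau_min, cfg)
  f2 <- predict_and_residual(zl_mut[[1]], t2, sel2$tau_min, cfg)
  expect_identical(c(f1$beta0, f1$beta1), c(f2$beta0, f2$beta1))
})

test_that("residuals isolate injected late components", {
  tmpl0 <- reference_template()
  set.seed(46)
  # exact template session: residual ~ 0 everywhere (template extension
  # holds its final value, matching the session's plateau)
  z <- session_from_template(tmpl0, 0, 1, 0, 0)
  f <- predict_and_residual(z, tmpl0, 0, cfg)
  expect_lt(max(abs(f$residual$values)), 1e-9)
  # injected late inhibition is recovered in the residual
  tt <- trace_times(z)
  late <- ifelse(tt >= 600 & tt <= 2400,
                 -1.5 * sin(pi * (tt - 600) / 1800), 0)
  z2 <- trace_with(z, z$values + late + rnorm(length(tt), 0, 0.05))
  f2 <- predict_and_residual(z2, tmpl0, 0, cfg)
  idx <- tt >= 0
  expect_gt(cor(f2$residual$values[idx], late[idx]), 0.9)
  # fit-window residual mean ~ 0 by construction
  fit_idx <- tt >= -1500 & tt <= 60
  expect_equal(mean(f2$residual$values[fit_idx]), 0, tolerance = 1e-9)
})

test_that("a doubled early inhibition doubles the fitted slope", {
  tmpl0 <- reference_template()
  set.seed(47)
  z1 <- session_from_template(tmpl0, 0, 1, 0, 0.05)
  z2 <- session_from_template(tmpl0, 0, 2, 0, 0.05)
  b1 <- fit_session(z1, tmpl0, 0)$beta1
  b2 <- fit_session(z2, tmpl0, 0)$beta1
  expect_equal(b2 / b1, 2, tolerance = 0.05)
})

test_that("residual window summaries report means and extrema with times", {
  tmpl0 <- reference_template()
  z <- session_from_template(tmpl0, 0, 1, 0, 0)
  f <- predict_and_residual(z, tmpl0, 0, cfg)
  s0 <- summarize_residual(f)
  expect_equal(s0$mean, c(0, 0), tolerance = 1e-9)
  # single dip of -2 at 20 min lands in the late window extremum
  tt <- trace_times(z)
  dip <- ifelse(abs(tt - 1200) <= 60, -2 * cos(pi * (tt - 1200) / 120)^2, 0)
  f2 <- predict_and_residual(trace_with(z, z$values + dip), tmpl0, 0, cfg)
  s2 <- summarize_residual(f2)
  expect_equal(s2$min[2], -2, tolerance = 1e-6)
  expect_equal(s2$min_time_s[2], 1200)
})
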