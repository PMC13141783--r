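# Lagged Spearman cross-correlation, pseudosession nulls and group
# significance.

cfg <- default_config()

test_that("identity and constructed delays are recovered exactly", {
  set.seed(51)
  x <- cumsum(rnorm(4000))
  tr <- make_trace(x)
  cg <- lagged_spearman(tr, tr, max_lag_s = 300, compensate = FALSE)
  expect_equal(cg$rho[cg$lag_s == 0], 1)
  expect_equal(cg$peak_lag_s, 0)
  # fp(t) = -bg(t - 300): extremal rho ~ -1 at +300 (fp follows bg)
  smooth <- as.numeric(stats::filter(rnorm(4300), rep(1 / 60, 60), sides = 1))
  smooth[is.na(smooth)] <- 0
  bg <- make_trace(smooth[301:4300])
  fp <- make_trace(-smooth[1:4000] + rnorm(4000, 0, 0.01))
  cg2 <- lagged_spearman(fp, bg, max_lag_s = 600, compensate = FALSE)
  expect_equal(cg2$peak_lag_s, 300, tolerance = 0.01)
  expect_lt(cg2$peak_rho, -0.95)
})

test_that("rank invariance: monotone transforms leave rho unchanged", {
  set.seed(52)
  x <- cumsum(rnorm(3000))
  y <- cumsum(rnorm(3000))
  a <- lagged_spearman(make_trace(x), make_trace(y), max_lag_s = 120,
                       compensate = FALSE)
  b <- lagged_spearman(make_trace(exp(x / 10)), make_trace(y^3),
                       max_lag_s = 120, compensate = FALSE)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("fast correlogram equals the brute-force loop", {
  set.seed(53)
  x <- rnorm(500)
  y <- rnorm(500)
  cg <- lagged_spearman(make_trace(x), make_trace(y), max_lag_s = 50,
                        min_overlap = 10, compensate = FALSE)
  expect_equal(cg$rho, brute_lagged_spearman(x, y, -50:50),
               tolerance = 1e-9)
})

test_that("symmetry: swapping the series mirrors the lag axis", {
  set.seed(54)
  x <- cumsum(rnorm(2000)); y <- cumsum(rnorm(2000))
  a <- lagged_spearman(make_trace(x), make_trace(y), max_lag_s = 100,
                       compensate = FALSE)
  b <- lagged_spearman(make_trace(y), make_trace(x), max_lag_s = 100,
                       compensate = FALSE)
  expect_equal(a$rho, rev(b$rho), tolerance = 1e-9)
})

test_that("short support errors; constant segments give NA", {
  set.seed(55)
  x <- rnorm(400)
  # support must cover 2 x max_lag + min_overlap
  expect_error(lagged_spearman(make_trace(x), make_trace(rnorm(400)),
                               max_lag_s = 130, min_overlap = 300,
                               compensate = FALSE), "too short")
  # a constant series has zero rank variance at every lag
  cg2 <- lagged_spearman(make_trace(rep(1, 400)), make_trace(x),
                         max_lag_s = 50, compensate = FALSE)
  expect_true(all(is.na(cg2$rho)))
  expect_true(is.na(cg2$peak_lag_s))
})

test_that("pseudosession nulls are seeded, centered and respect offsets", {
  set.seed(56)
  fp <- make_trace(cumsum(rnorm(4000)))
  donors <- lapply(1:3, function(i) make_trace(cumsum(rnorm(4000))))
  ne1 <- pseudosession_null(fp, donors, n_pairings = 30, min_offset_s = 600,
                            seed = 9, max_lag_s = 120, compensate = FALSE)
  ne2 <- pseudosession_null(fp, donors, n_pairings = 30, min_offset_s = 600,
                            seed = 9, max_lag_s = 120, compensate = FALSE)
  expect_identical(ne1$rho, ne2$rho) # determinism under a fixed seed
  expect_lt(abs(mean(ne1$rho, na.rm = TRUE)), 2 / sqrt(30) * 2)
  expect_error(pseudosession_null(fp, list(), 10), "other sessions")
  # min_offset = duration/2: a single admissible shift, deterministic
  short <- make_trace(rnorm(1000))
  donor <- list(make_trace(rnorm(1000)))
  na <- pseudosession_null(short, donor, n_pairings = 3, min_offset_s = 500,
                           seed = 1, max_lag_s = 60, compensate = FALSE)
  nb <- pseudosession_null(short, donor, n_pairings = 3, min_offset_s = 500,
                           seed = 2, max_lag_s = 60, compensate = FALSE)
  expect_identical(na$rho, nb$rho)
})

test_that("internal rank-sum p matches wilcox.test's normal approximation", {
  set.seed(57)
  for (i in 1:25) {
    x <- rnorm(sample(3:10, 1))
    y <- rnorm(sample(50:200, 1))
    if (i %% 3 == 0) y[1:5] <- y[6:10] # inject ties
    expect_equal(glycophot:::ranksum_p(x, y),
                 suppressWarnings(stats::wilcox.test(
                   x, y, exact = FALSE, correct = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("group significance flags a real shared correlation band", {
  set.seed(58)
  n <- 4000
  common <- as.numeric(stats::filter(rnorm(n + 200), rep(1 / 120, 120),
                                     sides = 1))
  common[is.na(common)] <- 0
  real <- list(); nulls <- list()
  donors_pool <- lapply(1:4, function(i) make_trace(cumsum(rnorm(n)) / 10))
  for (s in 1:5) {
    bgv <- common[1:n] + rnorm(n, 0, 0.05)
    fpv <- 0.8 * common[1:n] + rnorm(n, 0, 0.05)
    id <- paste0("S", s)
    real[[id]] <- lagged_spearman(make_trace(fpv), make_trace(bgv),
                                  max_lag_s = 300, compensate = FALSE)
    nulls[[id]] <- pseudosession_null(make_trace(fpv), donors_pool,
                                      n_pairings = 60, min_offset_s = 600,
                                      seed = s, max_lag_s = 300,
                                      compensate = FALSE)
  }
  gs <- group_significance(real, nulls, alpha = 0.01)
  expect_true(gs$significant[gs$lag_s == 0])
  expect_gt(gs$mean_rho[gs$lag_s == 0], 0.5)
  expect_true(all(gs$p_bh >= gs$p_raw, na.rm = TRUE))
  expect_equal(gs$family_size, sum(!is.na(gs$p_raw)))
  # all-zero correlations: no significant lags
  flat_real <- lapply(1:4, function(s) lagged_spearman(
    make_trace(rnorm(n)), make_trace(rnorm(n)), max_lag_s = 60,
    compensate = FALSE))
  names(flat_real) <- paste0("F", 1:4)
  flat_nulls <- lapply(1:4, function(s) pseudosession_null(
    make_trace(rnorm(n)), donors_pool, n_pairings = 40, min_offset_s = 600,
    seed = s + 10, max_lag_s = 60, compensate = FALSE))
  names(flat_nulls) <- names(flat_real)
  gs0 <- group_significance(flat_real, flat_nulls, alpha = 0.01)
  expect_lt(mean(gs0$significant), 0.02)
})

test_that("Benjamini-Hochberg rejects exactly the hand-computed set", {
  p <- c(0.001, 0.02, 0.03, 0.5)
  # step-up thresholds i*q/m for q = 0.05, m = 4
  adj <- p.adjust(p, method = "BH")
  expect_equal(which(adj <= 0.05), 1:3)
})

test_that("peak-lag comparison pairs sessions and degenerates gracefully", {
  a <- c(S1 = -600, S2 = -500, S3 = -550, S4 = -700)
  cmp0 <- peak_lag_compare(a, a)
  expect_equal(cmp0$diff_s, rep(0, 4))
  expect_true(cmp0$degenerate)
  expect_equal(cmp0$p_value, 1)
  b <- a + c(900, 800, 850, 1000)
  cmp <- peak_lag_compare(a, b)
  expect_true(all(cmp$diff_s > 0))
  expect_lt(cmp$p_value, 0.15) # minimal attainable two-sided p at n = 4
  expect_error(peak_lag_compare(a[1], (a + 5)[1]), "2 paired")
  expect_message(peak_lag_compare(a, b[1:3]), "unpaired")
})

test_that("quadratic refinement recovers an exact parabola vertex", {
  lag <- seq(-300, 300)
  rho <- -0.8 + ((lag - 42) / 500)^2
  expect_equal(refine_peak_lag(lag, rho, 150), 42, tolerance = 1e-6)
  # a monotone curve has no interior vertex: falls back to the discrete peak
  expect_equal(refine_peak_lag(lag, lag / 300 * 0.9, 150), -300)
})
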