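# Lagged rank (Spearman) cross-correlation between photometry and glucose
# series, pseudosession nulls from circularly shifted glucose of other
# sessions, and group-level aggregation (Fisher z averaging, per-lag
# rank-sum tests against the null, Benjamini-Hochberg control).
#
# Sign convention, stated on every output: positive lag means the
# photometry series FOLLOWS the glucose series.

# Linear cross-correlation sums c[L] = sum_t x[t] * y[t - L] for
# L = -(n-1)..(n-1), via zero-padded FFT.
crosscorr_sums <- function(x, y) {
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  Y <- stats::fft(c(y, numeric(nfft - n)))
  z <- Re(stats::fft(X * Conj(Y), inverse = TRUE)) / nfft
  # z[1 + L] holds lag L for L >= 0; negative lags wrap at nfft - |L| + 1.
  list(pos = z[1:n], neg = z[(nfft - n + 2):nfft]) # neg: L = -(n-1)..-1
}

#' Lagged Spearman cross-correlation
#'
#' Rank-transforms both full series once (average ranks for ties), then
#' computes, for each lag L on the 1-sample grid within `max_lag_s`, the
#' Pearson correlation of the overlapping segments of `fp(t)` and
#' `bg(t - L)`. The overlap shrinks with |L|; lags whose overlap falls
#' below `min_overlap` samples, or where a segment has zero rank variance,
#' are undefined (`NA`). Both traces must share the 1 Hz grid; they are
#' first aligned on their common time support (after compensating any
#' recorded causal-filter group delay when `compensate` is `TRUE`).
#'
#' @param fp Photometry-side `uniform_trace` (raw z, modeled, or residual).
#' @param bg Glucose-side `uniform_trace` (level or derivative).
#' @param max_lag_s Maximum lag in seconds (default 20 min).
#' @param min_overlap Minimum overlap in samples for a defined lag (120).
#' @param window_s Optional analysis window `c(start, end)` in seconds
#'   applied to both series after alignment (default 0-90 min).
#' @param compensate Compensate recorded causal group delays before
#'   aligning (default TRUE).
#' @return An object of class `correlogram`: `lag_s`, `rho`, `peak_lag_s`
#'   (lag of extremal |rho|, ties to the smallest |lag|), `peak_rho`, `n`.
#' @export
lagged_spearman <- function(fp, bg, max_lag_s = 1200, min_overlap = 120L,
                            window_s = NULL, compensate = TRUE) {
  stopifnot(inherits(fp, "uniform_trace"), inherits(bg, "uniform_trace"))
  if (abs(fp$fs - bg$fs) > 1e-12) stop("traces must share the sampling rate")
  if (compensate) {
    fp <- compensate_delay(fp)
    bg <- compensate_delay(bg)
  }
  # Align on common integer-second support.
  t_lo <- max(fp$t0, bg$t0)
  t_hi <- min(max(trace_times(fp)), max(trace_times(bg)))
  if (!is.null(window_s)) {
    t_lo <- max(t_lo, window_s[1])
    t_hi <- min(t_hi, window_s[2])
  }
  if (t_hi - t_lo < (2 * max_lag_s + min_overlap) / fp$fs)
    stop("overlapping support too short for the requested maximum lag")
  x <- trace_slice(fp, t_lo, t_hi)$values
  y <- trace_slice(bg, t_lo, t_hi)$values
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  max_l <- as.integer(round(max_lag_s * fp$fs))
  lags <- seq.int(-max_l, max_l)

  cc <- crosscorr_sums(rx, ry)
  csx <- cumsum(rx); csx2 <- cumsum(rx^2)
  csy <- cumsum(ry); csy2 <- cumsum(ry^2)
  sx_tot <- csx[n]; sx2_tot <- csx2[n]

  rho <- vapply(lags, function(L) {
    m <- n - abs(L)
    if (m < min_overlap) return(NA_real_)
    if (L >= 0) {
      sab <- cc$pos[1 + L]
      sa <- sx_tot - if (L > 0) csx[L] else 0
      sa2 <- sx2_tot - if (L > 0) csx2[L] else 0
      sb <- csy[m]; sb2 <- csy2[m]
    } else {
      sab <- cc$neg[n + L] # index n - |L|
      sa <- csx[m]; sa2 <- csx2[m]
      sb <- csy[n] - csy[-L]; sb2 <- csy2[n] - csy2[-L]
    }
    va <- sa2 - sa^2 / m
    vb <- sb2 - sb^2 / m
    if (va <= 0 || vb <= 0) return(NA_real_)
    (sab - sa * sb / m) / sqrt(va * vb)
  }, numeric(1))

  ok <- which(!is.na(rho))
  peak <- if (length(ok)) {
    o <- ok[order(-abs(rho[ok]), abs(lags[ok]), lags[ok])][1]
    o
  } else NA_integer_
  structure(
    list(lag_s = lags / fp$fs, rho = rho,
         peak_lag_s = if (is.na(peak)) NA_real_ else lags[peak] / fp$fs,
         peak_rho = if (is.na(peak)) NA_real_ else rho[peak],
         n = n, sign_convention = "positive lag = photometry follows glucose"),
    class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d lags, peak rho %.3f at %+.0f s (%s)\n",
              length(x$lag_s), x$peak_rho, x$peak_lag_s,
              x$sign_convention))
  invisible(x)
}

#' Pseudosession null ensemble
#'
#' Builds a null distribution of correlograms by pairing one session's
#' photometry trace with circularly shifted glucose traces from *other*
#' sessions: each pairing draws a donor session and a circular shift
#' uniform on `[min_offset, duration - min_offset]`, then computes a full
#' correlogram identically to the real analysis.
#'
#' @param fp The session's photometry-side `uniform_trace`.
#' @param other_bg List of glucose-side `uniform_trace`s from other
#'   sessions (at least one).
#' @param n_pairings Number of null pairings (default 100).
#' @param min_offset_s Minimum circular shift in seconds (default 20 min).
#' @param seed Integer seed.
#' @param ... Passed to [lagged_spearman()].
#' @return An object of class `null_ensemble`: `lag_s`, `rho` (matrix,
#'   pairings x lags), `n_pairings`.
#' @export
pseudosession_null <- function(fp, other_bg, n_pairings = 100L,
                               min_offset_s = 1200, seed = 1L, ...) {
  if (length(other_bg) < 1L)
    stop("no other sessions available for pseudosession pairing; ",
         "a within-session circular-shift fallback is not provided")
  set.seed(seed)
  rows <- vector("list", n_pairings)
  lag_s <- NULL
  for (i in seq_len(n_pairings)) {
    donor <- other_bg[[sample.int(length(other_bg), 1L)]]
    n <- length(donor$values)
    off_n <- as.integer(round(min_offset_s * donor$fs))
    if (n - 2L * off_n < 0L)
      stop("donor session too short for the minimum circular offset")
    shift <- if (n - 2L * off_n == 0L) off_n else
      sample(seq.int(off_n, n - off_n), 1L)
    shifted <- trace_with(donor, donor$values[((seq_len(n) - 1L + shift) %% n) + 1L])
    cg <- lagged_spearman(fp, shifted, ...)
    rows[[i]] <- cg$rho
    lag_s <- cg$lag_s
  }
  structure(list(lag_s = lag_s, rho = do.call(rbind, rows),
                 n_pairings = n_pairings, min_offset_s = min_offset_s),
            class = "null_ensemble")
}

# Two-sided Mann-Whitney rank-sum p-value, normal approximation with tie
# correction and continuity correction (the same approximation
# stats::wilcox.test uses for large samples); vastly faster for the
# hundreds of thousands of per-lag tests the null calibration requires.
ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(NA_real_)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  z <- w - nx * ny / 2
  nties <- table(r)
  sigma <- sqrt((nx * ny / 12) *
                ((nx + ny + 1) - sum(nties^3 - nties) /
                   ((nx + ny) * (nx + ny - 1))))
  if (sigma == 0) return(1)
  correction <- sign(z) * 0.5
  p <- 2 * stats::pnorm(-abs((z - correction) / sigma))
  min(1, p)
}

#' Group correlogram with pseudosession significance
#'
#' Per lag: Fisher-transforms each session's correlation, averages in
#' z-space and maps back to rho for display; computes a two-sided
#' rank-sum p-value comparing the real per-session correlations with the
#' pooled pseudosession null correlations at that lag; then controls the
#' false discovery rate across lags by Benjamini-Hochberg. Lags undefined
#' in any session are excluded from the BH family (family size recorded).
#'
#' @param real List of `correlogram`s (>= 3 sessions).
#' @param nulls List of `null_ensemble`s, one per session.
#' @param alpha Significance level on BH-adjusted p (default 0.01).
#' @return An object of class `group_correlogram`: `lag_s`, `mean_rho`,
#'   `p_raw`, `p_bh`, `significant`, `family_size`, `peak_lag_s`.
#' @export
group_significance <- function(real, nulls, alpha = 0.01) {
  if (length(real) < 3L) stop("need at least 3 sessions")
  if (length(nulls) != length(real))
    stop("one null ensemble per session is required")
  lag_s <- real[[1]]$lag_s
  rho_mat <- do.call(rbind, lapply(real, function(cg) {
    if (!identical(cg$lag_s, lag_s)) stop("correlogram lag grids differ")
    cg$rho
  }))
  null_mat <- do.call(rbind, lapply(nulls, function(ne) {
    if (!identical(ne$lag_s, lag_s)) stop("null ensemble lag grids differ")
    ne$rho
  }))
  clip <- function(r) pmin(pmax(r, -1 + 1e-6), 1 - 1e-6)
  if (any(abs(rho_mat) >= 1, na.rm = TRUE))
    warning("|rho| = 1 encountered; clipped before Fisher transform")
  zmean <- colMeans(atanh(clip(rho_mat)))
  mean_rho <- tanh(zmean)

  defined <- colSums(is.na(rho_mat)) == 0L
  p_raw <- rep(NA_real_, length(lag_s))
  for (j in which(defined)) {
    nv <- null_mat[, j]
    nv <- nv[!is.na(nv)]
    p_raw[j] <- ranksum_p(rho_mat[, j], nv)
  }
  p_bh <- rep(NA_real_, length(lag_s))
  p_bh[defined] <- stats::p.adjust(p_raw[defined], method = "BH")
  significant <- !is.na(p_bh) & p_bh < alpha
  ok <- which(!is.na(mean_rho) & defined)
  peak <- if (length(ok))
    ok[order(-abs(mean_rho[ok]), abs(lag_s[ok]), lag_s[ok])][1]
  else NA_integer_
  structure(
    list(lag_s = lag_s, mean_rho = mean_rho, p_raw = p_raw, p_bh = p_bh,
         significant = significant, family_size = sum(defined),
         alpha = alpha,
         peak_lag_s = if (is.na(peak)) NA_real_ else lag_s[peak],
         sign_convention = "positive lag = photometry follows glucose"),
    class = "group_correlogram")
}

#' Paired comparison of per-session peak lags
#'
#' Pairs per-session peak lags from two conditions (e.g. raw z vs
#' residual traces against the glucose derivative) by session ID, drops
#' sessions missing in either condition (logged), and runs a two-sided
#' Wilcoxon signed-rank test on the paired differences.
#'
#' @param a,b Named numeric vectors of per-session peak lags in seconds
#'   (names are session IDs).
#' @return List `sessions`, `lag_a_s`, `lag_b_s`, `diff_s` (b - a),
#'   `statistic`, `p_value`, `degenerate`.
#' @export
peak_lag_compare <- function(a, b) {
  common <- intersect(names(a), names(b))
  dropped <- setdiff(union(names(a), names(b)), common)
  if (length(dropped))
    message("peak_lag_compare: dropped unpaired session(s): ",
            paste(dropped, collapse = ", "))
  if (length(common) < 2L)
    stop("need at least 2 paired sessions")
  av <- a[common]; bv <- b[common]
  keep <- !is.na(av) & !is.na(bv)
  test <- paired_timing_test(av[keep], bv[keep])
  list(sessions = common[keep], lag_a_s = unname(av[keep]),
       lag_b_s = unname(bv[keep]), diff_s = unname(bv[keep] - av[keep]),
       statistic = test$statistic, p_value = test$p_value,
       degenerate = test$degenerate)
}

#' Refine a correlogram peak by local quadratic interpolation
#'
#' The rank-correlation trough of heavily smoothed physiological series is
#' broad, so the discrete argmax of |rho| jitters under noise. This helper
#' fits a quadratic to the correlation curve within `halfwidth_s` of the
#' discrete extremum and returns the vertex, a standard sub-grid peak
#' localization; the discrete peak is returned unchanged when the vertex
#' falls outside the fit window or the fit is degenerate.
#'
#' @param lag_s Lag grid in seconds.
#' @param rho Correlation per lag (NA allowed).
#' @param halfwidth_s Half-width of the fit window (default 180 s).
#' @return Refined peak lag in seconds.
#' @export
refine_peak_lag <- function(lag_s, rho, halfwidth_s = 180) {
  ok <- which(!is.na(rho))
  if (length(ok) < 5L) return(NA_real_)
  i0 <- ok[which.max(abs(rho[ok]))]
  sel <- which(lag_s >= lag_s[i0] - halfwidth_s &
                 lag_s <= lag_s[i0] + halfwidth_s & !is.na(rho))
  if (length(sel) < 5L) return(lag_s[i0])
  cf <- stats::coef(stats::lm(rho[sel] ~ lag_s[sel] + I(lag_s[sel]^2)))
  if (!is.finite(cf[3]) || cf[3] == 0) return(lag_s[i0])
  v <- unname(-cf[2] / (2 * cf[3]))
  if (!is.finite(v) || abs(v - lag_s[i0]) > halfwidth_s) lag_s[i0] else v
}
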