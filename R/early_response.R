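# Lagged template-regression model of the early (anticipatory) photometry
# response. The template is the across-session pointwise median of
# baseline-aligned z traces over the model window [-25, +1] min; each
# session is fit by OLS on a lag-shifted template over that window only,
# with the lag selected by subject-stratified K-fold cross-validation.
# Residuals (session minus prediction) isolate the second-phase response.

#' Extract a session's z values on the common model-window grid
#'
#' @param z A `uniform_trace` of Z_FP at 1 Hz.
#' @param window Numeric `c(t_start, t_end)` in seconds.
#' @return Numeric vector on the per-second grid `window[1]..window[2]`,
#'   or `NULL` when the session does not cover the window.
#' @keywords internal
window_grid_values <- function(z, window) {
  grid <- seq(window[1], window[2], by = 1 / z$fs)
  tt <- trace_times(z)
  idx <- round((grid - tt[1]) * z$fs) + 1
  if (any(idx < 1 | idx > length(z$values))) return(NULL)
  if (max(abs(tt[idx] - grid)) > 1e-6) return(NULL)
  z$values[idx]
}

#' Build the early-response template
#'
#' Pointwise across-session median of training-session z traces on the
#' model-window grid; the median makes the template robust to outlier
#' sessions. Sessions that do not cover the window are excluded with a
#' warning.
#'
#' @param z_list List of `uniform_trace` z traces (training sessions).
#' @param window Model window in seconds (default -25 to +1 min).
#' @return An object of class `early_template`: `values` on the grid,
#'   `time_s`, `n_sessions`.
#' @export
build_template <- function(z_list, window = c(-1500, 60)) {
  if (length(z_list) < 2L) stop("need at least 2 training sessions")
  rows <- lapply(z_list, window_grid_values, window = window)
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop))
    warning(sum(drop), " session(s) lacking model-window coverage excluded")
  rows <- rows[!drop]
  if (length(rows) == 0L) stop("no training session covers the model window")
  m <- do.call(rbind, rows)
  structure(
    list(values = apply(m, 2, stats::median),
         time_s = seq(window[1], window[2], by = 1),
         window = window, n_sessions = nrow(m)),
    class = "early_template")
}

# Template evaluated at times `at_s - tau_s`, with nearest-edge fill
# outside the defined window (beyond the end, the final value is held
# constant, so late residuals read as deviation from the early pattern's
# plateau).
shift_template <- function(template, at_s, tau_s) {
  src <- at_s - tau_s
  src <- pmin(pmax(src, template$time_s[1]),
              template$time_s[length(template$time_s)])
  idx <- round(src - template$time_s[1]) + 1
  template$values[idx]
}

#' Fit one session against a lag-shifted template
#'
#' Ordinary least squares of the session's z trace on
#' `template(t - tau)` over the fit window only; no sample after the
#' window end enters the fit.
#'
#' @param z Session z trace (`uniform_trace`).
#' @param template An `early_template`.
#' @param tau_min Lag in minutes (positive = template shifted later).
#' @param window Fit window in seconds (defaults to the template window).
#' @return List `beta0`, `beta1`, `mse`, `r2`.
#' @export
fit_session <- function(z, template, tau_min = 0, window = template$window) {
  yv <- window_grid_values(z, window)
  if (is.null(yv)) stop("session does not cover the fit window")
  xv <- shift_template(template, seq(window[1], window[2], by = 1),
                       tau_s = tau_min * 60)
  if (stats::var(xv) <= 0)
    stop("degenerate (constant) shifted template")
  b1 <- stats::cov(xv, yv) / stats::var(xv)
  b0 <- mean(yv) - b1 * mean(xv)
  resid <- yv - (b0 + b1 * xv)
  mse <- mean(resid^2)
  sst <- sum((yv - mean(yv))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  list(beta0 = b0, beta1 = b1, mse = mse, r2 = r2)
}

#' Subject-stratified cross-validation plan
#'
#' Assigns sessions to K folds keeping all sessions of a subject in the
#' same fold when possible (subjects are dealt round-robin to folds); with
#' a single subject a plain session-level K-fold is used with a warning.
#'
#' @param subjects Character/factor vector, one entry per training session.
#' @param k Fold count (default 5; reduced when fewer groups exist).
#' @return Integer fold assignment per session.
#' @export
make_cv_plan <- function(subjects, k = 5L) {
  n <- length(subjects)
  if (n < 2L) stop("need at least 2 sessions for cross-validation")
  subjects <- as.character(subjects)
  uniq <- unique(subjects)
  if (length(uniq) == 1L) {
    warning("single subject: stratification impossible, using plain K-fold")
    k <- min(k, n)
    return(rep_len(seq_len(k), n))
  }
  k <- min(k, length(uniq))
  fold_of_subject <- stats::setNames(rep_len(seq_len(k), length(uniq)), uniq)
  unname(fold_of_subject[subjects])
}

#' Select the template lag by inner cross-validation
#'
#' For each candidate lag, rebuilds the template from K-1 folds, fits each
#' left-out session, and accumulates validation mean-squared error. The
#' selected lag minimizes mean validation MSE; ties break to higher mean
#' validation R-squared, then to smaller absolute lag.
#'
#' @param z_list List of training-session z traces.
#' @param subjects Subject ID per training session.
#' @param config Configuration list (entry `early_model`: `tau_grid_min`,
#'   `k_folds`, `window_s`).
#' @return List `tau_min` (selected lag), `cv` (data frame of per-lag mean
#'   validation MSE and R-squared), `folds`.
#' @export
select_lag_cv <- function(z_list, subjects, config = default_config()) {
  em <- config$early_model
  if (length(z_list) != length(subjects))
    stop("z_list and subjects must have the same length")
  folds <- make_cv_plan(subjects, em$k_folds)
  if (length(unique(folds)) < 2L) stop("need at least 2 folds")
  tau_grid <- em$tau_grid_min
  window <- em$window_s
  res <- lapply(tau_grid, function(tau) {
    mses <- c(); r2s <- c()
    for (k in sort(unique(folds))) {
      train <- z_list[folds != k]
      if (length(train) < 2L) next
      tmpl <- build_template(train, window)
      for (z in z_list[folds == k]) {
        f <- fit_session(z, tmpl, tau_min = tau, window = window)
        mses <- c(mses, f$mse); r2s <- c(r2s, f$r2)
      }
    }
    c(mse = mean(mses), r2 = mean(r2s, na.rm = TRUE))
  })
  cv <- data.frame(tau_min = tau_grid,
                   mse = vapply(res, `[[`, numeric(1), "mse"),
                   r2 = vapply(res, `[[`, numeric(1), "r2"))
  # argmin MSE; ties -> higher R2 -> smaller |tau|. Order candidates so
  # that the first row under that ordering wins deterministically.
  ord <- order(cv$mse, -cv$r2, abs(cv$tau_min), cv$tau_min)
  list(tau_min = cv$tau_min[ord[1]], cv = cv, folds = folds)
}

#' Per-session prediction and residual traces
#'
#' Refits the session's intercept and slope on the fit window with the
#' selected lag fixed, then evaluates the prediction over the session's
#' full time axis (template held at its final value beyond the model
#' window) and forms the residual `R(t) = Z(t) - prediction(t)`.
#'
#' @param z Session z trace.
#' @param template An `early_template` built from all training sessions.
#' @param tau_min Selected lag in minutes.
#' @param config Configuration list.
#' @return An object of class `early_fit`: `beta0`, `beta1`, `tau_min`,
#'   `mse`, `r2`, `prediction` and `residual` (`uniform_trace`s on the
#'   session axis).
#' @export
predict_and_residual <- function(z, template, tau_min,
                                 config = default_config()) {
  em <- config$early_model
  f <- fit_session(z, template, tau_min = tau_min, window = em$window_s)
  tt <- trace_times(z)
  pred_v <- f$beta0 + f$beta1 * shift_template(template, tt, tau_min * 60)
  prediction <- trace_with(z, pred_v)
  residual <- trace_with(z, z$values - pred_v)
  structure(
    list(beta0 = f$beta0, beta1 = f$beta1, tau_min = tau_min,
         mse = f$mse, r2 = f$r2,
         prediction = prediction, residual = residual),
    class = "early_fit")
}

#' Windowed residual summaries
#'
#' Mean and extrema (with times) of the residual trace over analysis
#' windows, by default the early (0-10 min) and late (10-60 min)
#' post-delivery windows. The most negative residual marks peak residual
#' inhibition for timing comparisons.
#'
#' @param fit An `early_fit`.
#' @param windows_min List of `c(start, end)` windows in minutes.
#' @return A data frame with one row per window: `window`, `mean`, `min`,
#'   `min_time_s`, `max`, `max_time_s`.
#' @export
summarize_residual <- function(fit, windows_min = list(c(0, 10), c(10, 60))) {
  stopifnot(inherits(fit, "early_fit"))
  tt <- trace_times(fit$residual)
  rows <- lapply(windows_min, function(w) {
    idx <- which(tt >= w[1] * 60 - 1e-9 & tt <= w[2] * 60 + 1e-9)
    v <- fit$residual$values[idx]
    data.frame(window = sprintf("%g-%g min", w[1], w[2]),
               mean = mean(v),
               min = min(v), min_time_s = tt[idx[which.min(v)]],
               max = max(v), max_time_s = tt[idx[which.max(v)]])
  })
  do.call(rbind, rows)
}
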