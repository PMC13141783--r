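# Cohort-level statistics: subject fixed-effects OLS with robust standard
# errors, paired signed-rank timing comparisons, one-sample t-tests on
# anticipatory onsets, and the standard dose/metric regression battery.
# The experimental unit throughout is the session.

#' OLS with subject fixed effects and robust standard errors
#'
#' Fits `y ~ x + factor(subject) [+ covariates]` by ordinary least
#' squares and reports the slope of `x` with heteroskedasticity-robust
#' (HC3) standard errors and a 95% confidence interval. With a single
#' subject the fixed effects collapse to the intercept (with a warning),
#' leaving plain OLS. Collinear designs raise an error naming the
#' offending columns.
#'
#' @param y Numeric response, one value per session.
#' @param x Numeric predictor of interest.
#' @param subject Subject ID per session.
#' @param covariates Optional named list or data frame of additional
#'   numeric covariates (e.g. dose, baseline glucose).
#' @return An object of class `regression_result`: `slope`, `se`,
#'   `ci` (95%), `p_value`, `r2`, `n`, `covariates`.
#' @export
ols_fixed_effects <- function(y, x, subject, covariates = NULL) {
  keep <- stats::complete.cases(y, x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  y <- y[keep]; x <- x[keep]; subject <- as.character(subject)[keep]
  df <- data.frame(.y = y, .x = x)
  terms <- ".x"
  if (length(unique(subject)) > 1L) {
    df$.subject <- factor(subject)
    terms <- c(terms, ".subject")
  } else {
    warning("single subject: fixed effects collapse to the intercept")
  }
  if (!is.null(covariates)) {
    cv <- covariates[keep, , drop = FALSE]
    for (nm in names(cv)) df[[nm]] <- cv[[nm]]
    terms <- c(terms, names(cv))
  }
  if (nrow(df) <= length(terms) + 1L)
    stop("more parameters than sessions")
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("collinear design; offending columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC3"))
  est <- ct[".x", "Estimate"]
  se <- ct[".x", "Std. Error"]
  dfree <- fit$df.residual
  ci <- est + c(-1, 1) * stats::qt(0.975, dfree) * se
  structure(
    list(slope = est, se = se, ci = ci,
         p_value = ct[".x", "Pr(>|t|)"],
         r2 = summary(fit)$r.squared, n = nrow(df),
         covariates = setdiff(terms, ".x"), fit = fit),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> slope %.4g (HC3 SE %.3g, 95%% CI [%.4g, %.4g]), p = %.3g, R2 = %.3f, n = %d\n",
    x$slope, x$se, x$ci[1], x$ci[2], x$p_value, x$r2, x$n))
  invisible(x)
}

#' Paired signed-rank comparison of event times
#'
#' Two-sided Wilcoxon signed-rank test on paired per-session times; zero
#' differences are dropped (the standard convention). When all
#' differences are zero the comparison is degenerate and reported as such
#' with p = 1.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return List `statistic`, `p_value`, `n_pairs`, `n_dropped_zero`,
#'   `degenerate`.
#' @export
paired_timing_test <- function(a, b) {
  if (length(a) != length(b)) stop("unpaired lengths: ", length(a),
                                   " vs ", length(b))
  d <- b - a
  nz <- d != 0
  if (!any(nz))
    return(list(statistic = NA_real_, p_value = 1,
                n_pairs = length(d), n_dropped_zero = sum(!nz),
                degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(d[nz], alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = length(d), n_dropped_zero = sum(!nz), degenerate = FALSE)
}

#' One-sample t-test of onset times against zero
#'
#' Two-sided Student's one-sample t-test of the mean onset time against
#' 0, reporting mean and SEM; used for anticipatory-onset inference.
#'
#' @param onset_times Numeric vector (minutes), n >= 3.
#' @return List `t`, `p_value`, `mean`, `sem`, `n`, `degenerate`.
#' @export
onset_sign_test <- function(onset_times) {
  onset_times <- onset_times[!is.na(onset_times)]
  n <- length(onset_times)
  if (n < 3L) stop("need at least 3 onset times")
  if (stats::sd(onset_times) == 0)
    return(list(t = NA_real_, p_value = NA_real_,
                mean = mean(onset_times),
                sem = 0, n = n, degenerate = TRUE))
  tt <- stats::t.test(onset_times, mu = 0)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean = mean(onset_times),
       sem = stats::sd(onset_times) / sqrt(n), n = n, degenerate = FALSE)
}

#' Dose/metric regression battery
#'
#' Runs the standard battery of session-level fixed-effects regressions
#' relating glucose dose and glycemic metrics to each other and to the
#' photometry and early-model metrics: peak excursion, rise and fall
#' rates and iAUC against dose; peak z inhibition and clipped AUC against
#' dose and against the glycemic metrics; and early-model slope against
#' rise and fall rates (with dose and baseline glucose as covariates).
#'
#' @param table A cohort table as built by [build_cohort_table()]: one row
#'   per session with at least `subject`, `dose_g_per_kg` and the metric
#'   columns produced by the pipeline.
#' @return A tidy data frame, one row per regression: `response`,
#'   `predictor`, `covariates`, `n`, `slope`, `se`, `ci_lo`, `ci_hi`,
#'   `p_value`, `r2`.
#' @export
dose_metric_correlations <- function(table) {
  if (length(unique(table$dose_g_per_kg)) < 2L)
    stop("need at least 2 dose levels")
  specs <- list(
    list(y = "bg_peak_delta_g_mg_dl", x = "dose_g_per_kg"),
    list(y = "bg_peak_derivative_mg_dl_s", x = "dose_g_per_kg"),
    list(y = "bg_fall_derivative_mg_dl_s", x = "dose_g_per_kg"),
    list(y = "bg_iauc_mg_dl_min", x = "dose_g_per_kg"),
    list(y = "fp_peak_z", x = "dose_g_per_kg"),
    list(y = "fp_peak_z", x = "bg_peak_delta_g_mg_dl"),
    list(y = "fp_peak_z", x = "bg_peak_derivative_mg_dl_s"),
    list(y = "fp_peak_z", x = "bg_fall_derivative_mg_dl_s"),
    list(y = "fp_neg_auc_z_min", x = "dose_g_per_kg"),
    list(y = "beta1", x = "bg_peak_derivative_mg_dl_s",
         covariates = c("dose_g_per_kg", "bg_baseline_mg_dl")),
    list(y = "beta1", x = "bg_fall_derivative_mg_dl_s",
         covariates = c("dose_g_per_kg", "bg_baseline_mg_dl")))
  rows <- lapply(specs, function(s) {
    if (!all(c(s$y, s$x, s$covariates) %in% names(table))) return(NULL)
    cov_df <- if (is.null(s$covariates)) NULL
              else table[, s$covariates, drop = FALSE]
    res <- tryCatch(
      ols_fixed_effects(table[[s$y]], table[[s$x]], table$subject, cov_df),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) {
      res <- tryCatch(suppressWarnings(
        ols_fixed_effects(table[[s$y]], table[[s$x]], table$subject, cov_df)),
        error = function(e) NULL)
    }
    if (is.null(res)) return(NULL)
    data.frame(response = s$y, predictor = s$x,
               covariates = paste(s$covariates, collapse = "+"),
               n = res$n, slope = res$slope, se = res$se,
               ci_lo = res$ci[1], ci_hi = res$ci[2],
               p_value = res$p_value, r2 = res$r2)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
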