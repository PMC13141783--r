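# Session file format (CSV + JSON sidecar), cohort analysis orchestration
# and the end-to-end pipeline writer.
#
# A session on disk is `<stem>.csv` with columns time_s, fp_signal,
# fp_reference, bg_mg_dl (1 Hz, time strictly increasing in 1-s steps)
# and `<stem>.json` with subject_id, dose_g_per_kg, route, order_index
# and units.

#' Write a session to disk
#'
#' @param session A session list with elements `id`, `meta`, `bg`,
#'   `fp_signal`, `fp_reference` (the three traces aligned).
#' @param stem Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_session <- function(session, stem) {
  df <- data.frame(
    time_s = trace_times(session$bg),
    fp_signal = session$fp_signal$values,
    fp_reference = session$fp_reference$values,
    bg_mg_dl = session$bg$values)
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  # Full double precision so a round trip is lossless.
  out <- df
  for (nm in names(out)) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.table(out, csv, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(session$meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read and validate a session
#'
#' Validation errors name the offending row and column: all four data
#' columns must be present, numeric and NA-free, and `time_s` must
#' increase in exact 1/fs steps.
#'
#' @param stem Path without extension (expects `<stem>.csv` and
#'   `<stem>.json`).
#' @return A session list (`id`, `meta`, `bg`, `fp_signal`,
#'   `fp_reference`).
#' @export
read_session <- function(stem) {
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  if (!file.exists(csv)) stop("missing data file: ", csv)
  if (!file.exists(json)) stop("missing sidecar: ", json)
  df <- utils::read.csv(csv)
  required <- c("time_s", "fp_signal", "fp_reference", "bg_mg_dl")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col))
    stop("missing column(s) in ", csv, ": ",
         paste(missing_col, collapse = ", "))
  for (nm in required) {
    bad <- which(!is.finite(df[[nm]]))
    if (length(bad))
      stop(sprintf("non-finite value in %s, column %s, row %d",
                   basename(csv), nm, bad[1]))
  }
  dt <- diff(df$time_s)
  fs <- 1 / stats::median(dt)
  bad <- which(abs(dt - 1 / fs) > 1e-6)
  if (length(bad))
    stop(sprintf("non-uniform time grid in %s at row %d (step %.6g s)",
                 basename(csv), bad[1] + 1L, dt[bad[1]]))
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  if (!is.null(meta$dose_g_per_kg) && meta$dose_g_per_kg < 0)
    stop("dose must be >= 0 in ", json)
  t0 <- df$time_s[1]
  list(id = meta$session_id %||% basename(stem),
       meta = meta,
       bg = uniform_trace(df$bg_mg_dl, t0 = t0, fs = fs),
       fp_signal = uniform_trace(df$fp_signal, t0 = t0, fs = fs),
       fp_reference = uniform_trace(df$fp_reference, t0 = t0, fs = fs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read all sessions in a cohort directory
#'
#' @param dir Directory of `<id>.csv` + `<id>.json` session pairs.
#' @return Named list of session objects.
#' @export
read_cohort <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  stems <- sub("\\.csv$", "", csvs)
  stems <- stems[file.exists(paste0(stems, ".json"))]
  if (length(stems) == 0L) stop("no session files found in ", dir)
  sessions <- lapply(stems, read_session)
  names(sessions) <- vapply(sessions, `[[`, character(1), "id")
  sessions
}

#' Analyze a cohort of sessions in memory
#'
#' Runs the full analysis chain over a list of sessions: per-session
#' glucose and photometry preprocessing and metrics; the early-response
#' model (template from the training doses, lag selection by
#' cross-validation, per-session fits and residuals); lagged
#' cross-correlation of the residual and of the raw z trace against the
#' glucose derivative at the analysis dose, with pseudosession nulls,
#' group significance and the peak-lag comparison; and the cohort
#' regression battery. Per-session failures are recorded and skipped;
#' the run fails only when every session fails.
#'
#' @param sessions Named list of session objects (see [read_session()]).
#' @param config Configuration list.
#' @param seed Integer seed governing all stochastic steps (spectral and
#'   coupling nulls).
#' @return A list of class `cohort_results`: `table` (one row per
#'   session), `template`, `tau_min`, `cv`, `fits`, `coupling`, `stats`,
#'   `errors`, `config`, `seed`.
#' @export
analyze_cohort <- function(sessions, config = default_config(), seed = 1L) {
  if (length(sessions) == 0L) stop("no sessions to analyze")
  set.seed(seed)
  session_seeds <- stats::setNames(
    sample.int(2^30, length(sessions)), names(sessions))
  errors <- list()
  per <- list()
  for (id in names(sessions)) {
    sess <- sessions[[id]]
    res <- tryCatch({
      g <- preprocess_glucose(sess$bg, config)
      th <- onset_thresholds(g, z = config$glucose$onset_z)
      onset <- detect_bg_onset(g, th, sustain = config$glucose$onset_sustain_s)
      gm <- excursion_summary(g, onset, config)
      fp <- preprocess_photometry(sess$fp_signal, sess$fp_reference,
                                  config, label = id)
      grow <- glucose_metrics_row(gm)
      prow <- photometry_metrics_row(fp, gm$peak_time_s, config,
                                     seed = session_seeds[[id]])
      list(g = g, fp = fp, gm = gm,
           row = cbind(data.frame(session_id = id,
                                  subject = sess$meta$subject_id,
                                  dose_g_per_kg = sess$meta$dose_g_per_kg,
                                  order_index = sess$meta$order_index %||% NA),
                       grow, prow))
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[id]] <- conditionMessage(res)
    else per[[id]] <- res
  }
  if (length(per) == 0L)
    stop("all sessions failed: ",
         paste(names(errors), unlist(errors), sep = ": ", collapse = "; "))
  table <- do.call(rbind, lapply(per, `[[`, "row"))
  rownames(table) <- NULL

  # Early-response model.
  em <- config$early_model
  train_ids <- names(per)[table$dose_g_per_kg %in% em$training_doses]
  template <- NULL; tau <- NA_real_; cv <- NULL; fits <- list()
  if (length(train_ids) >= 2L) {
    z_train <- lapply(per[train_ids], function(p) p$fp$z)
    subj_train <- table$subject[match(train_ids, table$session_id)]
    sel <- suppressWarnings(select_lag_cv(z_train, subj_train, config))
    tau <- sel$tau_min; cv <- sel$cv
    template <- build_template(z_train, em$window_s)
    fits <- lapply(per, function(p)
      predict_and_residual(p$fp$z, template, tau, config))
    summ <- lapply(names(fits), function(id) {
      f <- fits[[id]]
      sr <- summarize_residual(f, em$residual_windows_min)
      data.frame(session_id = id, beta0 = f$beta0, beta1 = f$beta1,
                 tau_min = f$tau_min, fit_r2 = f$r2,
                 resid_early_mean = sr$mean[1],
                 resid_late_mean = sr$mean[2],
                 resid_late_min = sr$min[2],
                 resid_late_min_time_s = sr$min_time_s[2])
    })
    table <- merge(table, do.call(rbind, summ), by = "session_id",
                   sort = FALSE)
  }

  # Coupling at the analysis dose, against the glucose derivative: the
  # early-model prediction carries the anticipatory (phase 1) component,
  # the residual carries the second phase.
  cp <- config$coupling
  coupling <- NULL
  cpl_ids <- names(per)[abs(table$dose_g_per_kg[
    match(names(per), table$session_id)] - cp$analysis_dose) < 1e-9]
  if (length(cpl_ids) >= 3L && length(fits) > 0L) {
    derivs <- lapply(per[cpl_ids], function(p) p$g$derivative)
    run_side <- function(get_fp, window_s) {
      real <- list(); nulls <- list()
      for (id in cpl_ids) {
        fp_tr <- get_fp(id)
        real[[id]] <- lagged_spearman(
          fp_tr, derivs[[id]], max_lag_s = cp$max_lag_s,
          min_overlap = cp$min_overlap, window_s = window_s,
          compensate = cp$compensate_delay)
        nulls[[id]] <- pseudosession_null(
          fp_tr, derivs[setdiff(cpl_ids, id)],
          n_pairings = cp$n_pairings, min_offset_s = cp$min_offset_s,
          seed = session_seeds[[id]],
          max_lag_s = cp$max_lag_s, min_overlap = cp$min_overlap,
          window_s = window_s, compensate = cp$compensate_delay)
      }
      group <- group_significance(real, nulls, alpha = cp$alpha)
      list(real = real, nulls = nulls, group = group,
           peak_lags = vapply(real, `[[`, numeric(1), "peak_lag_s"))
    }
    modeled_side <- run_side(function(id) fits[[id]]$prediction, cp$window_s)
    resid_side <- run_side(function(id) fits[[id]]$residual,
                           cp$residual_window_s)
    cmp <- tryCatch(peak_lag_compare(modeled_side$peak_lags,
                                     resid_side$peak_lags),
                    error = function(e) NULL)
    coupling <- list(modeled = modeled_side, residual = resid_side,
                     peak_lag_comparison = cmp)
  }

  stats_tbl <- tryCatch(dose_metric_correlations(table),
                        error = function(e) NULL)
  structure(
    list(table = table, template = template, tau_min = tau, cv = cv,
         fits = fits, coupling = coupling, stats = stats_tbl,
         errors = errors, config = config, seed = seed),
    class = "cohort_results")
}

#' Run the end-to-end pipeline over a cohort directory
#'
#' Reads every session in `cohort_dir`, runs [analyze_cohort()] and
#' writes: `session_metrics.tsv` (one row per session), per-session early
#' fit JSONs and residual CSVs, the template CSV, group correlogram CSVs,
#' `statistics.tsv`, and `run_log.json` (resolved configuration, its MD5
#' hash, the master seed and any per-session errors). Outputs contain no
#' timestamps, so a rerun with the same inputs, configuration and seed
#' reproduces the results tree bit-identically.
#'
#' @param cohort_dir Directory of session files.
#' @param out_dir Results directory (created).
#' @param config Configuration list.
#' @param seed Master seed.
#' @return Invisibly, the `cohort_results` object.
#' @export
run_pipeline <- function(cohort_dir, out_dir, config = default_config(),
                         seed = 1L) {
  sessions <- read_cohort(cohort_dir)
  res <- analyze_cohort(sessions, config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  write_tsv(res$table, "session_metrics.tsv")
  if (!is.null(res$stats)) write_tsv(res$stats, "statistics.tsv")
  if (!is.null(res$template))
    write_tsv(data.frame(time_s = res$template$time_s,
                         template_z = res$template$values),
              "early_template.csv")
  if (length(res$fits)) {
    fit_dir <- file.path(out_dir, "early_fits")
    dir.create(fit_dir, showWarnings = FALSE)
    for (id in names(res$fits)) {
      f <- res$fits[[id]]
      jsonlite::write_json(
        list(session_id = id, beta0 = f$beta0, beta1 = f$beta1,
             tau_min = f$tau_min, r2 = f$r2, mse = f$mse),
        file.path(fit_dir, paste0(id, ".json")),
        auto_unbox = TRUE, digits = NA)
      utils::write.table(
        data.frame(time_s = trace_times(f$residual),
                   residual_z = sprintf("%.10g", f$residual$values)),
        file.path(fit_dir, paste0(id, "_residual.csv")),
        sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(res$coupling)) {
    for (side in c("modeled", "residual")) {
      g <- res$coupling[[side]]$group
      utils::write.table(
        data.frame(lag_s = g$lag_s, mean_rho = sprintf("%.10g", g$mean_rho),
                   p_raw = sprintf("%.10g", g$p_raw),
                   p_bh = sprintf("%.10g", g$p_bh),
                   significant = g$significant),
        file.path(out_dir, paste0("correlogram_", side, ".csv")),
        sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  jsonlite::write_json(
    list(seed = seed, config_md5 = unname(tools::md5sum(cfg_path)),
         n_sessions = length(sessions),
         n_failed = length(res$errors), errors = res$errors,
         tau_min = res$tau_min),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
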