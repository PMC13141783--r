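# Seeded generator of synthetic paired photometry + glucose sessions.
#
# The generator embodies the statistical structure the analysis assumes:
# dose-scaled glycemic excursions whose rise and fall rates grow with dose
# (so recovery times are roughly dose-invariant), an anticipatory
# stereotyped neural inhibition beginning minutes before gavage with
# dose-invariant amplitude (present only after prior glucose exposure), a
# second-phase inhibition driven by the delayed, rectified glucose rate of
# change, and realistic nuisance structure (telemetry spikes,
# photobleaching drift, motion artifacts shared between photometry
# channels). Every session stores its clean ground truth for
# parameter-recovery tests.

#' Glycemia generator parameters
#'
#' @param baseline Baseline glucose in mg/dL.
#' @param peak_per_dose Peak excursion in mg/dL per g/kg of dose.
#' @param rise_rate_per_dose Rise rate in (mg/dL/min) per (g/kg).
#' @param fall_rate_per_dose Fall rate in (mg/dL/min) per (g/kg). With
#'   both rates proportional to dose, rise/fall durations - and hence
#'   recovery times - are dose-invariant while peak and rates scale.
#' @param onset_delay_min Excursion onset after gavage, minutes.
#' @param plateau_min Plateau duration at peak, minutes.
#' @param corner_s Half-width of the cosine blends that round the upper
#'   corners of the excursion (the onset corner stays sharp so the stored
#'   onset is exact), seconds.
#' @param noise_sd Additive Gaussian noise SD, mg/dL.
#' @param spike_rate_per_min Poisson rate of telemetry dropout spikes.
#' @param spike_amp_mg_dl Range of absolute spike amplitudes, mg/dL.
#' @return A list of class `glycemia_params`.
#' @export
glycemia_params <- function(baseline = 130, peak_per_dose = 60,
                            rise_rate_per_dose = 6, fall_rate_per_dose = 2,
                            onset_delay_min = 3, plateau_min = 5,
                            corner_s = 60, noise_sd = 2,
                            spike_rate_per_min = 0.2,
                            spike_amp_mg_dl = c(20, 60)) {
  p <- as.list(environment())
  if (p$baseline <= 0) stop("baseline must be positive")
  if (p$rise_rate_per_dose < 0 || p$fall_rate_per_dose < 0 ||
      p$peak_per_dose < 0)
    stop("rates and peak scaling must be non-negative")
  structure(p, class = "glycemia_params")
}

#' Neural generator parameters
#'
#' @param phase1_amplitude Anticipatory trough depth in z units
#'   (dose-invariant when `phase1_dose_invariant` is TRUE).
#' @param phase1_onset_mean_min,phase1_onset_sd_min Anticipatory onset
#'   distribution (minutes relative to gavage; mean -4, SD 1).
#' @param phase1_fall_min Duration of the anticipatory descent, minutes.
#'   Within the session horizon the anticipatory inhibition is modeled as
#'   sustained (a plateau at the trough); set `phase1_recovery_tau_min`
#'   finite to add a slow exponential recovery.
#' @param phase1_recovery_tau_min Recovery time constant, minutes
#'   (`Inf` = sustained).
#' @param phase1_dose_invariant Keep the anticipatory amplitude
#'   independent of dose.
#' @param phase2_gain Second-phase gain in z per (mg/dL/min), applied to
#'   the rectified positive glucose derivative.
#' @param phase2_fall_gain Gain applied to the falling (negative)
#'   derivative, z per (mg/dL/min). With `phase2_fall_gain = phase2_gain`
#'   (the default) the second phase tracks the signed rate of change:
#'   inhibition deepens while glucose rises and relaxes back toward the
#'   anticipatory plateau while it falls. Zero gives a rectified
#'   rising-only drive; negative values deepen inhibition during the
#'   decline instead.
#' @param phase2_lag_s Delay of the second-phase drive behind the glucose
#'   derivative, seconds (default +300).
#' @param noise_sd Signal-channel measurement noise SD (z-like units).
#' @param reference_noise_sd Reference-channel noise SD; the isosbestic
#'   channel is considerably less noisy than the activity channel, which
#'   also keeps the attenuation bias of the reference regression (noisy
#'   regressor leaving residual bleach in the corrected trace) small.
#' @param baseline_sd,baseline_tau_min SD and correlation time of the slow
#'   Ornstein-Uhlenbeck baseline fluctuation of the latent neural trace
#'   (hunger-state variability); this component sets the baseline
#'   variability against which responses are z-scored.
#' @param bleach_amp,bleach_tau_min Photobleaching drift amplitude and
#'   time constant.
#' @param artifact_amp Amplitude of the slow motion artifact shared
#'   between signal and reference channels.
#' @param artifact_smooth_s Smoothing window of the shared artifact.
#' @param signal_offset,reference_offset Channel offsets (a.u.).
#' @param reference_gain Scale of the shared component in the reference
#'   channel relative to the signal channel.
#' @return A list of class `neural_params`.
#' @export
neural_params <- function(phase1_amplitude = 2.5,
                          phase1_onset_mean_min = -4,
                          phase1_onset_sd_min = 1,
                          phase1_fall_min = 3.5,
                          phase1_recovery_tau_min = Inf,
                          phase1_dose_invariant = TRUE,
                          phase2_gain = 0.12,
                          phase2_fall_gain = 0.12,
                          phase2_lag_s = 300,
                          noise_sd = 0.3, reference_noise_sd = 0.1,
                          baseline_sd = 0.3, baseline_tau_min = 5,
                          bleach_amp = 1.5, bleach_tau_min = 30,
                          artifact_amp = 2, artifact_smooth_s = 30,
                          signal_offset = 100, reference_offset = 80,
                          reference_gain = 0.8) {
  structure(as.list(environment()), class = "neural_params")
}

#' Cohort design
#'
#' @param n_subjects Number of subjects.
#' @param doses Doses in g/kg (0 = water).
#' @param sessions_per_dose Sessions per subject and dose.
#' @param span_s Session span `c(start, end)` in seconds.
#' @param master_seed Master seed; every session seed derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 6, doses = c(0, 0.5, 1, 2, 2.5),
                        sessions_per_dose = 1, span_s = c(-1500, 5400),
                        master_seed = 1L) {
  structure(as.list(environment()), class = "cohort_spec")
}

# Clean dose-scaled excursion on a time axis (seconds): a trapezoid with
# linear rise/fall and a plateau at the peak. The three upper corners are
# rounded with quadratic Bezier blends of half-width corner_s (tangent to
# the adjoining linear pieces); the onset corner stays sharp so the
# stored onset time is exact.
clean_excursion <- function(tt, dose, p) {
  if (dose <= 0) return(numeric(length(tt)))
  peak <- p$peak_per_dose * dose
  rise_s <- peak / (p$rise_rate_per_dose * dose) * 60
  fall_s <- peak / (p$fall_rate_per_dose * dose) * 60
  t_on <- p$onset_delay_min * 60
  t_pk <- t_on + rise_s
  t_fall <- t_pk + p$plateau_min * 60
  t_end <- t_fall + fall_s
  lin <- function(t) {
    ifelse(t <= t_on, 0,
    ifelse(t <= t_pk, peak * (t - t_on) / rise_s,
    ifelse(t <= t_fall, peak,
    ifelse(t <= t_end, peak * (1 - (t - t_fall) / fall_s), 0))))
  }
  y <- lin(tt)
  c2 <- min(p$corner_s, rise_s / 2, fall_s / 2, p$plateau_min * 30)
  for (tc in c(t_pk, t_fall, t_end)) {
    near <- which(tt > tc - c2 & tt < tc + c2)
    if (length(near) == 0L) next
    s <- (tt[near] - tc + c2) / (2 * c2) # 0..1 across the blend
    y[near] <- (1 - s)^2 * lin(tc - c2) + 2 * s * (1 - s) * lin(tc) +
      s^2 * lin(tc + c2)
  }
  pmax(y, 0)
}

#' Simulate a continuous glucose trace
#'
#' Baseline plus a dose-scaled excursion (see [glycemia_params()]),
#' additive Gaussian noise and Poisson-timed single-sample telemetry
#' spikes. The clean trace and the true onset, peak and rates are stored
#' in the `truth` attribute.
#'
#' @param params A `glycemia_params` object.
#' @param dose Dose in g/kg (0 = water).
#' @param span_s Session span `c(start, end)` in seconds.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz (default 1).
#' @return A `uniform_trace` (mg/dL) with attribute `truth`: list
#'   `clean` (uniform_trace), `onset_s` (NA for water), `peak_delta_g`,
#'   `rise_rate_mg_dl_min`, `fall_rate_mg_dl_min`.
#' @export
simulate_bg <- function(params, dose, span_s = c(-1500, 5400), seed = 1L,
                        fs = 1) {
  stopifnot(inherits(params, "glycemia_params"))
  set.seed(seed)
  tt <- seq(span_s[1], span_s[2], by = 1 / fs)
  clean_v <- params$baseline + clean_excursion(tt, dose, params)
  if (any(clean_v < 0))
    stop("parameters yield negative glucose")
  n <- length(tt)
  y <- clean_v + stats::rnorm(n, 0, params$noise_sd)
  n_spk <- stats::rpois(1, params$spike_rate_per_min * (tt[n] - tt[1]) / 60)
  if (n_spk > 0) {
    at <- sample.int(n, min(n_spk, n))
    amp <- stats::runif(length(at), params$spike_amp_mg_dl[1],
                        params$spike_amp_mg_dl[2]) *
      sample(c(-1, 1), length(at), replace = TRUE)
    y[at] <- y[at] + amp
  }
  out <- uniform_trace(y, t0 = tt[1], fs = fs)
  attr(out, "truth") <- list(
    clean = uniform_trace(clean_v, t0 = tt[1], fs = fs),
    onset_s = if (dose > 0) params$onset_delay_min * 60 else NA_real_,
    peak_delta_g = if (dose > 0) params$peak_per_dose * dose else 0,
    rise_rate_mg_dl_min = if (dose > 0) params$rise_rate_per_dose * dose
                          else NA_real_,
    fall_rate_mg_dl_min = if (dose > 0) params$fall_rate_per_dose * dose
                          else NA_real_)
  out
}

# Anticipatory (first-phase) shape: cosine descent from 0 to -amplitude
# between onset and onset + fall duration, then a plateau at the trough
# (optionally relaxing with time constant recovery_tau).
phase1_shape <- function(tt, onset_s, amplitude, fall_s, recovery_tau_s) {
  y <- numeric(length(tt))
  falling <- tt > onset_s & tt <= onset_s + fall_s
  s <- (tt[falling] - onset_s) / fall_s
  y[falling] <- -amplitude * (1 - cos(pi * s)) / 2
  after <- tt > onset_s + fall_s
  if (is.finite(recovery_tau_s)) {
    y[after] <- -amplitude * exp(-(tt[after] - onset_s - fall_s) /
                                   recovery_tau_s)
  } else {
    y[after] <- -amplitude
  }
  y
}

#' Simulate a photometry session coupled to a glucose trace
#'
#' The latent neural trace (z-like units) is the sum of a slow
#' Ornstein-Uhlenbeck baseline fluctuation, an anticipatory first phase
#' (present only after prior glucose exposure, i.e. when
#' `order_index > 1` or `prior_exposure` is set; amplitude dose-invariant
#' by default) and a second phase tracking the delayed glucose rate of
#' change (see `phase2_fall_gain` for the drive during the decline). The observed signal channel adds photobleaching
#' drift and a slow motion artifact shared with the reference channel,
#' plus independent channel noise.
#'
#' @param bg A `uniform_trace` from [simulate_bg()] (its `truth`
#'   attribute supplies the clean glucose trace).
#' @param params A `neural_params` object.
#' @param dose Dose in g/kg.
#' @param order_index Position of this session in the subject's session
#'   order (1 = first exposure).
#' @param seed Integer seed.
#' @param prior_exposure Force the anticipatory phase on/off; default
#'   `order_index > 1`.
#' @return List `signal`, `reference` (`uniform_trace`s) with attribute
#'   `truth`: `neural` (clean latent trace), `phase1_onset_min`,
#'   `phase1_amplitude`, `phase2_gain`, `phase2_lag_s`.
#' @export
simulate_fp <- function(bg, params, dose = 0, order_index = 2L, seed = 1L,
                        prior_exposure = order_index > 1L) {
  stopifnot(inherits(params, "neural_params"))
  truth_bg <- attr(bg, "truth")
  if (is.null(truth_bg)) stop("bg must carry a truth attribute")
  set.seed(seed + 1L)
  clean <- truth_bg$clean
  tt <- trace_times(clean)
  n <- length(tt)
  fs <- clean$fs

  phase1_onset <- stats::rnorm(1, params$phase1_onset_mean_min,
                               params$phase1_onset_sd_min)
  amp <- params$phase1_amplitude
  if (!params$phase1_dose_invariant) amp <- amp * (0.5 + 0.5 * dose)
  p1 <- if (prior_exposure)
    phase1_shape(tt, phase1_onset * 60, amp, params$phase1_fall_min * 60,
                 params$phase1_recovery_tau_min * 60)
  else numeric(n)

  # Second phase: driven by the low-frequency glucose rate of change
  # (mg/dL/min), delayed by phase2_lag_s. The rate is the clean level
  # passed through the same robust low-frequency estimator the analysis
  # uses (2-min causal boxcar, finite difference, 60-s causal average),
  # re-aligned to physical time: neural transduction integrates the rate
  # over minutes rather than sensing an instantaneous derivative.
  lvl <- causal_moving_average(clean, 120L)
  dtr <- compensate_delay(finite_difference_derivative(lvl, 60L))
  d <- dtr$values * 60
  d <- c(d, rep(d[length(d)], n - length(d)))
  drive <- params$phase2_gain * pmax(d, 0) -
    params$phase2_fall_gain * pmax(-d, 0)
  lag_n <- as.integer(round(params$phase2_lag_s * fs))
  drive_lagged <- c(numeric(min(lag_n, n)), drive)[seq_len(n)]
  p2 <- -drive_lagged

  # Slow physiological baseline fluctuation (OU process).
  a <- exp(-1 / (params$baseline_tau_min * 60 * fs))
  ou <- numeric(n)
  innov <- stats::rnorm(n, 0, params$baseline_sd * sqrt(1 - a^2))
  ou[1] <- stats::rnorm(1, 0, params$baseline_sd)
  for (i in 2:n) ou[i] <- a * ou[i - 1] + innov[i]

  neural <- p1 + p2 + ou
  bleach <- params$bleach_amp * exp(-(tt - tt[1]) /
                                      (params$bleach_tau_min * 60))
  raw_art <- stats::rnorm(n, 0, 1)
  k <- max(1L, as.integer(round(params$artifact_smooth_s * fs)))
  artifact <- params$artifact_amp *
    as.numeric(stats::filter(raw_art, rep(1 / k, k), sides = 1))
  artifact[is.na(artifact)] <- 0
  shared <- bleach + artifact
  sig <- params$signal_offset + neural + shared +
    stats::rnorm(n, 0, params$noise_sd)
  ref <- params$reference_offset + params$reference_gain * shared +
    stats::rnorm(n, 0, params$reference_noise_sd)
  out <- list(signal = uniform_trace(sig, t0 = tt[1], fs = fs),
              reference = uniform_trace(ref, t0 = tt[1], fs = fs))
  attr(out, "truth") <- list(
    neural = uniform_trace(neural, t0 = tt[1], fs = fs),
    phase1_onset_min = if (prior_exposure) phase1_onset else NA_real_,
    phase1_amplitude = if (prior_exposure) amp else 0,
    phase2_gain = params$phase2_gain,
    phase2_lag_s = params$phase2_lag_s)
  out
}

#' Generate a seeded synthetic cohort
#'
#' Writes one CSV + JSON sidecar per session (see [write_session()]) and a
#' tab-separated ground-truth manifest, fully determined by the master
#' seed. Dose order is randomized independently per subject; the
#' anticipatory phase is present from each subject's second session on.
#'
#' @param spec A `cohort_spec`.
#' @param glyc A `glycemia_params`.
#' @param neural A `neural_params`.
#' @param dir Output directory (created if missing); `NULL` keeps the
#'   cohort in memory only.
#' @return Invisibly, a list with `sessions` (list of session objects,
#'   each with a `truth` attribute) and `manifest` (data frame; one row
#'   per session with the stored ground truth).
#' @export
generate_cohort <- function(spec = cohort_spec(), glyc = glycemia_params(),
                            neural = neural_params(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$master_seed)
  subject_ids <- sprintf("M%02d", seq_len(spec$n_subjects))
  session_seeds <- sample.int(2^30, spec$n_subjects * length(spec$doses) *
                                spec$sessions_per_dose)
  sessions <- list()
  manifest <- list()
  si <- 0L
  for (s in seq_len(spec$n_subjects)) {
    dose_vec <- rep(spec$doses, spec$sessions_per_dose)
    dose_order <- dose_vec[sample.int(length(dose_vec))]
    for (oi in seq_along(dose_order)) {
      si <- si + 1L
      dose <- dose_order[oi]
      id <- sprintf("%s_o%02d", subject_ids[s], oi)
      seed_i <- session_seeds[si]
      bg <- simulate_bg(glyc, dose, spec$span_s, seed = seed_i)
      fp <- simulate_fp(bg, neural, dose = dose, order_index = oi,
                        seed = seed_i)
      truth_bg <- attr(bg, "truth")
      truth_fp <- attr(fp, "truth")
      sess <- list(
        id = id,
        meta = list(session_id = id, subject_id = subject_ids[s],
                    dose_g_per_kg = dose, route = "OG", order_index = oi,
                    seed = seed_i, units = list(bg = "mg/dL", fp = "a.u.")),
        bg = bg, fp_signal = fp$signal, fp_reference = fp$reference)
      attr(sess, "truth") <- c(truth_bg[-1], truth_fp[-1],
                               list(clean_bg = truth_bg$clean,
                                    neural = truth_fp$neural))
      if (!is.null(sessions[[id]])) stop("session ID collision: ", id)
      sessions[[id]] <- sess
      manifest[[si]] <- data.frame(
        session_id = id, subject_id = subject_ids[s], dose_g_per_kg = dose,
        order_index = oi, seed = seed_i,
        true_onset_s = truth_bg$onset_s,
        true_peak_delta_g = truth_bg$peak_delta_g,
        true_rise_rate_mg_dl_min = truth_bg$rise_rate_mg_dl_min,
        true_fall_rate_mg_dl_min = truth_bg$fall_rate_mg_dl_min,
        true_phase1_onset_min = truth_fp$phase1_onset_min,
        true_phase1_amplitude = truth_fp$phase1_amplitude,
        true_phase2_gain = truth_fp$phase2_gain,
        true_phase2_lag_s = truth_fp$phase2_lag_s)
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sess in sessions)
      write_session(sess, file.path(dir, sess$id))
    utils::write.table(manifest, file.path(dir, "truth_manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(sessions = sessions, manifest = manifest))
}
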