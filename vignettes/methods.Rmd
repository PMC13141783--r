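---
title: "Models and methods: decomposing AgRP photometry responses to an oral glucose load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycophot)
```

## The problem

Hypothalamic AgRP neurons are rapidly inhibited by food and nutrient
cues. When their population calcium activity is recorded by fiber
photometry alongside continuous arterial glucose at 1 Hz around an oral
glucose gavage (t = 0), the inhibition has two functionally distinct
parts: a stereotyped *anticipatory* drop that begins minutes before the
gavage and does not scale with dose, and a *second phase* that tracks
the glycemic excursion — specifically the rate of blood-glucose change,
with neural activity lagging the rate signal by several minutes.
`glycophot` implements the full analysis chain needed to make that
decomposition quantitative on paired photometry + glucose sessions, and
a seeded synthetic-cohort generator so that every stage can be validated
against known ground truth without any recorded data.

## Preprocessing

Both streams share one robust chain: MAD despiking (k = 2), a 7-sample
centered median filter, and a 60-sample causal moving average. Causal
smoothing is used deliberately: it never leaks post-event samples into
the pre-event period, at the cost of a known group delay of
(window − 1)/2 samples, which each trace records in its metadata.

Two points deserve emphasis:

* **Despiking reference.** The threshold rule compares deviations with
  k × MAD. Measured from the *global* median, any real excursion
  (ΔG up to ~150 mg/dL) dwarfs the MAD and would itself be flagged and
  interpolated away. The preprocessing chains therefore measure
  deviations from a short (7-sample) centered running median, which
  isolates genuine impulsive artifacts — telemetry dropouts, motion
  spikes — while leaving slow physiology untouched. The primitive
  (`despike_mad`) still offers the global rule, with a guard for the
  degenerate MAD = 0 case (nothing is flagged unless a sample deviates
  beyond a tiny absolute tolerance, so constant traces pass through).
* **Group-delay bookkeeping.** The glucose derivative passes a 2-min
  causal boxcar, a finite difference and a 60-s causal average
  (≈ 89 s of accumulated delay); the photometry z trace only the 60-s
  average (≈ 30 s). Timing-sensitive analyses (the lagged
  cross-correlations) first advance each trace by its rounded recorded
  delay (`compensate_delay`), so lags are estimated on a common
  physical time axis. Scalar metrics (onset, peak times) are reported
  on the causal axis, as acquired.

Photometry additionally gets the isosbestic correction (ordinary
least-squares regression of the reference channel on the signal channel,
subtracting the fit) before despiking, a zero-phase Butterworth low-pass
(4-min cutoff period, order 3; the `signal::butter` design applied
forward and backward, with odd-reflection padding of six cutoff periods
at both ends so the zero-state transients of each pass settle inside
the padding rather than corrupting the trace edges) after smoothing,
and finally a z-score against the −25..0 min baseline. Heavy low-pass filtering shrinks the baseline SD,
so z magnitudes from this chain are larger than z-scores of raw traces;
all inferences are relative, so only the display scale is affected.

## Glycemic metrics

The excursion ΔG(t) is the smoothed level minus the −25..0 min baseline
median. Onset is declared by a two-condition detector evaluated on the
onset branch (local −5..0 min baseline): the smoothed derivative must
exceed `m_d + 3·σ̂_d`, or the *unsmoothed* level must exceed `3·σ̂_y`
(robust scales = 1.4826 × MAD of the pre-event segment), for 60
consecutive samples. The level condition deliberately uses the
unsmoothed series: on the heavily smoothed level the samples of a
1-min run are almost perfectly correlated and the sustain requirement
loses its meaning — the detector then fires on ~18% of null sessions,
versus ~1% with the unsmoothed level (the calibration target is ≤ 5%).

Remaining metrics: peak ΔG (0–90 min) and its time; peak derivative in
0–30 min; rate of fall as the most negative post-peak derivative;
half-max recovery interpolated on the despiked-but-unsmoothed series;
a plateau (smoothed derivative within ±10% of the peak rise derivative
for ≥ 2 min, a band fraction the source methods leave unquantified —
exposed in the configuration); return to baseline (first ΔG ≤ 0, or a
sustained relaxation of the derivative above −10% of the peak rise
derivative after decline has begun); and the positive-only iAUC over
0–90 min (trapezoidal).

## The early-response model

The anticipatory component is captured by a lagged template regression.
The template is the pointwise across-session *median* of baseline-aligned
z traces over the model window (−25 to +1 min), making it robust to
outlier sessions. Each session is then fit by OLS,

Z(t) ≈ β0 + β1 · template(t − τ),  t ∈ [−25, +1] min,

with the lag τ picked from a ±1 min grid in 0.25-min steps by K-fold
cross-validation over training sessions (K = 5, folds stratified by
subject; K is not stated in the source methods, 5 is the conventional
default). For each candidate lag the template is rebuilt from K−1 folds
and the left-out sessions are scored by validation MSE; ties break to
higher validation R², then to the smaller |τ|. Only pre/early data ever
enter the template, the betas, or the lag — an invariant the test suite
asserts by mutating post-window data and requiring bit-identical fits.

One structural point: a cohort in which *every* training session is
shifted by a common lag yields a rebuilt template carrying the same
shift, so the cross-validated lag is correctly 0 — the CV lag is
*relative* to the cohort's own template. Recovery of a generative shift
is therefore only identifiable against a fixed external template, which
is how the validation experiments measure it.

Per-session intercepts and slopes are refit with τ\* fixed (the slope
β1 is used downstream as a per-session "baseline state" metric, so it
must be session-level; a pooled fit is not provided). The prediction is
extended over the whole session by holding the template's final value
constant beyond the model window: the early pattern is
glucose-trajectory-independent, so late residuals read as deviation from
the early pattern's plateau. Residuals R(t) = Z(t) − prediction are the
second-phase estimate; they are summarized over 0–10 and 10–60 min
windows (mean, extrema with times).

Because the lag grid spans only ±1 min while anticipatory onsets vary
session-to-session (SD ≈ 1 min in the generator), sessions whose onset
falls outside the grid leave a small template-mismatch transient around
the descent. This is confined to roughly ±3 min of the gavage and
motivates the residual coupling window below.

## Coupling analysis

Lagged Spearman cross-correlation: both series are rank-transformed once
(average ranks), and for every lag on the 1-s grid within ±20 min the
Pearson correlation of the overlapping segments is computed. The sums
needed for all 2401 lags are obtained from cumulative sums and one FFT
cross-correlation of the rank series, so a full correlogram is
O(n log n); the test suite verifies exact agreement (≤ 1e−9) with a
plain-loop implementation. The sign convention is fixed and stated on
every output: positive lag = photometry follows glucose.

Specificity is assessed with pseudosession nulls: each session's
photometry trace is paired with circularly shifted glucose traces from
*other* sessions (shift ≥ 20 min, uniform; 100 pairings per session by
default). Group summaries Fisher-transform per-session correlations,
average in z-space, and back-transform for display. Per lag, a two-sided
rank-sum test compares the real per-session correlations against the
pooled null correlations; p-values are then Benjamini–Hochberg corrected
across the defined-lag family (undefined lags — zero rank variance — are
excluded and the family size recorded), with significance at adjusted
p < 0.01. The rank-sum p uses an internal tie- and continuity-corrected
normal approximation identical to the one `stats::wilcox.test` applies
at these sample sizes (verified against it in the tests); the
calibration experiments run hundreds of thousands of per-lag tests, for
which `wilcox.test`'s per-call overhead is prohibitive.

Two analysis windows are used. The *modeled* (prediction) trace — the
phase-1 carrier — is correlated over the full session including the
pre-event period, since the anticipatory descent **is** its signal;
restricting to post-gavage data would reduce the prediction to a
constant plateau with undefined timing. The *residual* trace is
correlated from +3 min onward: the model window ends at +1 min, the
template can be shifted by up to +1 min, and the zero-phase low-pass
spreads the descent by about half a cutoff period more, so +3 min is
the first time the residual is free of early-pattern structure. The
exact start was calibrated on synthetic cohorts with a known generative
lag (the estimate is biased ≈ +15 s when the window starts at +2 min
and ≈ −25 s from +6 min, and near zero at +3 min) and then frozen.

The correlogram trough of rank-correlated, heavily smoothed series is
broad — its depth changes by ~1% over ±2 min of lag — so the discrete
argmax jitters under noise. `refine_peak_lag` fits a local quadratic
(±3 min) around the discrete extremum and returns the vertex, the
standard sub-grid localization for broad correlation peaks. Even so,
group-level lag estimates on realistic cohorts carry a standard
deviation of ~20–30 s with occasional heavier-tailed excursions driven
by slow baseline fluctuations; a ±30 s recovery band is at the edge of
what these study conditions support, and the acceptance suite reports
the honest rate.

## Cohort statistics

The experimental unit is the session. Paired timing comparisons use the
two-sided Wilcoxon signed-rank test (zero differences dropped; all-zero
comparisons reported as degenerate with p = 1); anticipatory onsets are
tested against zero with a one-sample t-test (mean ± SEM reported).
Continuous relationships use OLS with subject fixed effects and
heteroskedasticity-robust (HC3) standard errors; requests for
mixed-effects adjustments are served by the same fixed-effects OLS with
dose and baseline glucose as covariates, a deterministic approximation
noted in the output. `dose_metric_correlations` runs the standard
battery (glycemic metrics and photometry metrics against dose and
against each other, plus the early-model slope against the rates with
dose/baseline covariates) into one tidy table.

## The synthetic-session generator

`simulate_bg` builds a dose-scaled excursion: a trapezoid with linear
rise and fall whose *rates* scale with dose (6 and 2 (mg/dL/min)/(g/kg))
while the peak scales as 60 mg/dL per g/kg — so rise/fall durations and
recovery times are dose-invariant, matching the qualitative structure of
oral dosing. Upper corners are rounded by quadratic Bézier blends; the
onset corner stays sharp so the stored onset (3 min after gavage) is
exact. Gaussian noise (2 mg/dL) and Poisson telemetry spikes complete
the trace; the clean trace and all true parameters ride along in a
`truth` attribute and in the cohort manifest.

`simulate_fp` composes the latent neural trace from three parts, in
z-like units:

* a slow Ornstein–Uhlenbeck baseline fluctuation (SD 0.3, τ = 5 min),
  representing hunger-state variability; it provides the physiological
  variance against which baseline z-scoring is meaningful;
* an anticipatory phase (present only after prior glucose exposure,
  i.e. from each subject's second session on): a cosine descent of
  dose-invariant depth 2.5 beginning at a session-specific onset
  (mean −4 min, SD 1 min) and lasting 3.5 min, then held at the trough
  for the rest of the session. Within a 115-min session the anticipatory
  inhibition is modeled as sustained; an optional recovery time constant
  exists but defaults to infinity, because any recovery not present in
  the ≤ +1 min template would masquerade as second-phase structure. The
  descent duration places the trough near the gavage, slightly earlier
  than in vivo reports, so the early pattern completes within the model
  window — a deliberate trade of trough latency for a well-defined
  residual null;
* a second phase equal to −gain × the *smoothed* glucose rate of change
  (the same 2-min boxcar + 60-s estimator the analysis uses, re-aligned
  to physical time), delayed by 300 s, with gain 0.12 z/(mg/dL/min) on
  the rising side and, by default, the same gain on the falling side —
  i.e. the phase tracks the signed rate: inhibition deepens while
  glucose rises and relaxes back toward the anticipatory plateau while
  it falls (never rising above baseline, because phase 1 holds). A
  smoothed drive is the physiological choice — transduction through
  gut–brain signaling integrates over minutes — and it is what makes the
  300-s lag identifiable by the analysis at 1-s resolution. Setting the
  fall gain to 0 gives a rectified rising-only drive; a negative value
  deepens inhibition during the decline instead, but makes the drive
  non-monotone in the derivative and the generative lag unidentifiable
  by rank correlation.

The observed channels add exponential photobleaching (amplitude 1.5,
τ = 30 min) and a slow motion artifact (amplitude 2) shared between
signal and reference (reference scaled 0.8), plus independent channel
noise (0.3 signal, 0.1 reference). The cleaner reference mirrors real
isosbestic recordings and keeps the attenuation bias of the OLS
reference regression small: a noisy regressor leaves a fraction
σ²/(g²·V + σ²) of the shared drift in the corrected trace, and that
shared-sign residue measurably corrupts pseudosession-null calibration
when the reference is as noisy as the signal channel.

**What passing tests do and do not show.** The generator reproduces the
statistical structure the analysis assumes — dose scaling, a
dose-invariant anticipatory phase, rate-tracking with a fixed lag,
shared artifacts, spikes, bleach — but not GCaMP indicator kinetics,
meal-related behavior, sensor calibration drift, or the terminal return
of neural activity to baseline after the excursion. Passing the suite
demonstrates that the pipeline recovers known structure under realistic
noise; it does not certify effect sizes on recorded data.

## Numerical choices and degenerate inputs

* MAD = 0 in despiking: threshold treated as infinite except beyond an
  absolute guard (1e−9·|median| + 1e−12); all-flagged traces error.
* Constant reference channel: intercept-only fallback (mean
  subtraction); constant shifted template: error.
* Fisher transform at |rho| = 1: clipped to 1 − 1e−6 with a warning.
* Median-filter edges shrink symmetrically; the causal average shortens
  its window at the start; the derivative pads its leading sample with 0.
* Onset absence is a value (`NA`), not an error; sessions without onset
  are excluded from timing statistics but keep their AUC metrics.
* All randomness (generator, pseudo-onsets, null pairings, fold
  assignment) flows from explicit integer seeds; the pipeline derives
  per-session seeds from one master seed, and a rerun reproduces the
  results tree bit-identically.

## Problem sizes used in validation

The test suite simulates its own data throughout: 100 randomized
instances per primitive for oracle equivalence; 200 + 200 sessions for
onset calibration; 50 seeded cohorts for lag/slope recovery and for
coupling-lag recovery (18 sessions each); 10 cohorts for residual gain
ordering; 100 five-session cohorts for coupling null calibration and
200 sessions for spectral-p calibration. These sizes keep the full
suite within tens of minutes on a single core while leaving Monte-Carlo
margins that the assertions account for explicitly.

## Known limitations

* The ±1 min lag grid cannot absorb anticipatory onset variability
  beyond it; the resulting template mismatch is confined to the early
  minutes but contributes session-level noise to β1.
* Group-level coupling lags are identifiable only to a few tens of
  seconds under realistic baseline fluctuations (see above).
* The spectral band (periods 14–20 min) contains a single spectrogram
  bin at the 20-min window length, so band power is effectively a
  single-frequency statistic. Its rank p is mildly anticonservative by
  construction: the 5-min guard removes from the null exactly the
  pseudo-onsets most correlated with the evaluated value (band power is
  autocorrelated over the 20-min window length, far beyond the guard),
  and baseline-anchored z-scoring additionally pins variance near the
  event. Measured P(p ≤ 0.05) is ≈ 0.07–0.08 on stationary noise with
  the default guard, and ≈ 0.04 with the guard removed; treat the
  detector's per-bin p as descriptive rather than exact.
* The fixed-effects OLS approximation to mixed models is deterministic
  and matches the dominant specification of the source analyses, but it
  does not model subject-level slope variability.
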