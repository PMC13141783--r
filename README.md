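# glycophot

Joint analysis of fiber-photometry and continuous arterial glucose time
series around an oral glucose gavage.

## The problem

AgRP neurons in the hypothalamic arcuate nucleus are rapidly inhibited
by nutrient cues. Recording their population calcium activity (465 nm
signal + 405 nm isosbestic reference, 1 Hz) simultaneously with arterial
blood glucose around an oral gavage at t = 0 reveals a two-phase
response: a stereotyped **anticipatory inhibition** that begins minutes
before the gavage and does not scale with the glucose dose, and a
**second phase** that tracks the glycemic excursion — specifically the
blood-glucose *rate of change* dG/dt, which neural activity follows at a
positive lag of several minutes. `glycophot` turns that decomposition
into a reproducible pipeline for anyone analyzing paired
photometry + CGM sessions.

## What the package computes

- **Robust preprocessing** shared by both streams: MAD despiking
  (|y − ref| > k·MAD, k = 2, deviations from a short running median),
  7-sample centered median filter, 60-s causal moving average; the
  photometry stream additionally gets isosbestic reference regression, a
  zero-phase Butterworth low-pass (4-min period, order 3) and a baseline
  (−25..0 min) z-score Z(t).
- **Glycemic metrics**: ΔG(t), a sustained two-threshold onset detector
  (derivative > m_d + 3σ̂_d or level > 3σ̂_y for ≥ 60 s, robust scales
  σ̂ = 1.4826·MAD of the pre-event segment), peak ΔG, rates of rise and
  fall, interpolated half-max recovery, plateau, return to baseline,
  positive-only iAUC.
- **Photometry metrics**: peak z inhibition, clipped and total AUCs, a
  band-power (14–20 min periods) spectral onset against jittered
  pseudo-onset nulls, and the aperiodic 1/f^κ spectral exponent.
- **Early-response model**: per-session lagged template regression
  `Z(t) ≈ β0 + β1·template(t − τ)` fit on −25..+1 min only; the template
  is the across-session median, τ is selected on a ±1 min grid by
  subject-stratified K-fold cross-validation, and residuals
  `R(t) = Z(t) − prediction` isolate the second phase.
- **Coupling analysis**: lagged Spearman cross-correlation over ±20 min
  (positive lag = photometry follows glucose), circular-shift
  pseudosession nulls from other sessions' glucose, Fisher-z group
  averaging, per-lag rank-sum tests with Benjamini–Hochberg control.
- **Cohort statistics**: subject fixed-effects OLS with HC3 robust
  standard errors, Wilcoxon signed-rank timing comparisons, one-sample
  onset tests, and a tidy dose/metric regression battery.
- **A seeded synthetic-cohort generator** that writes session CSVs and a
  ground-truth manifest, so the entire pipeline is testable end to end
  with no recorded data.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and known limitations.

## Worked example

```r
library(glycophot)

co  <- generate_cohort(cohort_spec(n_subjects = 4, master_seed = 42))
cfg <- default_config()
cfg$coupling$n_pairings <- 30L          # lighter nulls for a quick look
res <- analyze_cohort(co$sessions, cfg, seed = 1)

head(res$table[, c("session_id", "dose_g_per_kg", "bg_onset_s",
                   "bg_peak_delta_g_mg_dl", "fp_peak_z", "beta1")], 5)
#>   session_id dose_g_per_kg bg_onset_s bg_peak_delta_g_mg_dl fp_peak_z   beta1
#> 1    M01_o01           1.0        226                  60.5     -6.66 -0.0477
#> 2    M01_o02           2.5        189                 150.6     -6.36  1.1138
#> 3    M01_o03           0.5        238                  30.9     -3.46  1.0886
#> 4    M01_o04           2.0        195                 120.5    -11.81  0.8800
#> 5    M01_o05           0.0         NA                   1.2     -5.17  0.8497

res$coupling$modeled$group$peak_lag_s    # anticipatory trace LEADS dG/dt
#> [1] -1050
res$coupling$residual$group$peak_lag_s   # residual FOLLOWS dG/dt (truth +300 s)
#> [1] 470

ols_fixed_effects(res$table$bg_peak_derivative_mg_dl_s * 60,
                  res$table$dose_g_per_kg, res$table$subject)
#> <regression_result> slope 6.029 (HC3 SE 0.0523, 95% CI [5.918, 6.141]),
#>                     p = 1.58e-23, R2 = 0.999, n = 20
```

Reading the output: glucose onsets land ~3–4 min after gavage and peak
excursions scale ~60 mg/dL per g/kg (the generator's construction,
recovered by the pipeline; the rate-of-rise slope of 6.03
(mg/dL/min)/(g/kg) matches the generative 6). The early-model slope β1
is ≈ 1 for every session with an anticipatory phase and ≈ 0 for
`M01_o01`, the subject's first exposure, which has none. The modeled
(anticipatory) trace peaks at a negative lag — it *leads* the glucose
derivative — while the residual peaks at a positive lag near the
generative +300 s; with only four dose-2 sessions the group peak is
noisy (470 s here), which is why validation uses larger cohorts and the
quadratic peak refinement (`refine_peak_lag`).

To run from a shell: `Rscript inst/scripts/run_pipeline.R simulate
<cohort_dir> --seed 42`, then `Rscript inst/scripts/run_pipeline.R all
<cohort_dir> <results_dir> --seed 1`. The results directory holds the
per-session metrics TSV, early-model JSONs and residual CSVs, group
correlograms, the statistics table, and a run log with the resolved
configuration hash; identical inputs, configuration and seed reproduce
it bit for bit.

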