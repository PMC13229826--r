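# poincareHRV

Short-term heart-rate variability (HRV) analysis built around the Poincaré
plot: an end-to-end R pipeline from a raw single-lead ECG to a two-group
biostatistical report, for researchers asking whether the *spatial* structure
of the RR-interval scatter carries discriminative information that
conventional HRV metrics miss — for example when probing autonomic signatures
of disease states such as lymph-node metastasis in oncology cohorts.

## What it computes

Given a 5-minute ECG (or a precomputed RR-interval series), the pipeline runs:

1. **R-peak detection** — an adaptive Pan–Tompkins chain: 5–15 Hz zero-phase
   Butterworth bandpass, five-point differencing, squaring, 150 ms
   moving-window integration, adaptive signal/noise thresholds with T-wave
   rejection (0.36 s window), refractory period (0.2 s), search-back, and
   apex refinement within ±150 ms of each candidate.
2. **Quality control** — intervals outside [0.3, 2.0] s discarded; adjacent
   pairs with relative change > 20% removed as ectopic/artifact clusters;
   recordings losing > 50% of beats excluded.
3. **Smoothness-priors detrending** — trend τ = (I + λ²D₂ᵀD₂)⁻¹z with
   λ = 500, difference order 2; metrics are computed on both the cleaned
   ("raw") and detrended series.
4. **The 16-metric panel** —
   time domain: SDNN, RMSSD;
   frequency domain (Welch, 4 Hz resampling, 256-pt Hamming, 50% overlap,
   1024-pt FFT): LF (0.04–0.15 Hz), HF (0.15–0.40 Hz), LF/HF;
   entropy: ApEn, SampEn (m = 2, r = 0.2·SD);
   Poincaré ellipse: SD1 = √(Var(ΔRR)/2), SD2 = √(2·Var(RR) − Var(ΔRR)/2),
   SD1/SD2;
   heart-rate asymmetry, each reported as |X − 50| with X the accelerating
   share in percent: PI (point counts), GI (vertical distances |y − x|),
   SI (phase angles |45° − atan2(y, x)|), AI (sector areas r²θ/2);
   grid metrics: GDR (occupied-cell fraction) and GDE (occupancy Shannon
   entropy, nats) averaged over all n × n grids for n = 100…200.
5. **Group statistics** — Shapiro–Wilk-gated t / Mann–Whitney tests with
   Cohen's *d* and 95% CI; ANCOVA adjusting for age, menopause, PR and Ki-67
   status with partial η²; ROC and stratified 10-fold cross-validated ROC
   (univariable logistic scoring, Youden operating point).

A synthetic-data module generates tachograms with controllable LF/HF content,
slow trends, successive-difference skewness (the heart-rate-asymmetry dial),
ectopic-beat artifacts, template-based ECG traces with known R-peak truth,
and full two-group cohorts (defaults: 142 + 76 subjects with realistic
covariate distributions), so the entire pipeline is testable and calibratable
without any patient data.

## Worked example

```r
library(poincareHRV)

# a 5-minute synthetic subject at ~73 bpm
rr <- generate_rri(rri_gen_params(seed = 42))
#> <rri_series:raw> 365 intervals, mean RR 0.820 s

# detect beats on a noisy synthesized ECG of that tachogram
ecg   <- synthesize_ecg(rr, fs = 400, noise_sd = 0.05, twave_amp = 0.2, seed = 42)
peaks <- detect_rpeaks(ecg)
#> <rpeak_set> 366 peaks @ 400 Hz

res <- run_subject(rr)   # QC -> detrend -> 16 metrics x 2 conditions
subset(res$metrics, metric %in% c("sdnn", "sd1", "sd2", "ai", "gdr", "gde"))
#>    condition metric       value
#> 1        raw   sdnn 27.17208211
#> 8        raw    sd1 15.51241371
#> 9        raw    sd2 35.15692127
#> 14       raw     ai  0.27147024
#> 15       raw    gdr  0.01769000
#> 16       raw    gde  5.86216442
#> 17 detrended   sdnn 23.82622741
#> 24 detrended    sd1 15.50638703
#> 25 detrended    sd2 29.91538377
#> 30 detrended     ai  2.70920016
#> 31 detrended    gdr  0.01781669
#> 32 detrended    gde  5.87048438
```

Reading the output: SDNN ≈ 27 ms and SD2 ≈ 35 ms drop after detrending while
SD1 is untouched — the slow trend contributes long-term, not beat-to-beat,
variability. The area index AI jumps from 0.27 to 2.71 because the detrended
condition evaluates the origin-referenced Poincaré geometry on the zero-mean
residual, which magnifies acceleration/deceleration asymmetry. GDR ≈ 0.018
says ~1.8% of grid cells are occupied at these resolutions, and GDE ≈ 5.9 is
near its ln(N) saturation — ~360 beats scatter into almost entirely distinct
cells.

A whole cohort run (statistics tables, provenance JSON) is one call:

```r
cohort <- generate_cohort(cohort_gen_params(ai_effect = 0.4, seed = 7))
mpath  <- write_cohort(cohort, "cohort_dir")
result <- run_cohort(mpath, pipeline_config(seed = 7), out = "cohort_out")
result$report$ancova      # covariate-adjusted group effects
result$report$roc         # apparent + cross-validated AUC
```

There is also a thin CLI (`inst/cli/hrv.R`) with `run-subject`, `run-cohort`
and `simulate-cohort` subcommands; see the script header for usage.

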