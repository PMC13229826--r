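---
title: "Poincaré graphical HRV metrics: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poincaré graphical HRV metrics: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`poincareHRV` implements a complete short-term heart-rate-variability (HRV)
pipeline for 5-minute single-lead ECG recordings: R-peak detection, RR-interval
(RRI) quality control, smoothness-priors detrending, a 16-metric panel
(time-domain, frequency-domain, entropy, and Poincaré graphical metrics), and a
two-group biostatistics layer (normality-gated tests with Cohen's *d*,
covariate-adjusted ANCOVA with partial η², cross-validated ROC). A synthetic
data module generates ECGs, tachograms and whole two-group cohorts with
controllable structure, so every stage is testable without patient data.

This vignette records the models, the conventions adopted where the field
offers more than one, and the reasoning behind the genuinely open design
choices. Nothing here reports an empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

# R-peak detection

Detection follows the Pan–Tompkins chain: a 5–15 Hz Butterworth bandpass
(order 3, applied forward–backward so the filtered trace is zero-phase and
stays aligned with the energy signal), the classic five-point derivative
kernel `y[n] = (2x[n] + x[n-1] - x[n-3] - 2x[n-4])/8`, squaring, and a 150 ms
moving-average integration. Candidate peaks of the energy signal are screened
by:

* adaptive signal/noise level estimates `SPKI`/`NPKI` updated with weights
  1/8–7/8, threshold `NPKI + 0.25 (SPKI − NPKI)`;
* a 0.2 s minimum peak interval and a 0.2 s refractory period;
* a T-wave rule: a candidate arriving within 0.36 s of the previous accepted
  peak is rejected when its maximal absolute slope is below 50% of the
  previous peak's — the canonical criterion, since only the window length is
  standardized in the literature;
* a search-back pass at half threshold whenever no peak is accepted within
  1.66× the running RR estimate.

Each accepted candidate is relocated to the local maximum of the *absolute
bandpassed* signal within ±150 ms. Using the bandpassed rather than the raw
trace keeps refinement robust to baseline wander; on noiseless synthetic
fixtures the median apex error is at most one sample (property-tested).
Because every threshold is derived from running signal statistics, detection
is exactly invariant to global amplitude scaling (also property-tested).
Indices are 0-based; times are `index / fs`.

# RR-interval quality control

Two rules are applied in order. Intervals outside [0.3, 2.0] s are discarded
unconditionally as physiologically implausible at rest. Then, on the spliced
series, any adjacent pair whose relative change `|RR[i+1] − RR[i]| / RR[i]`
exceeds 20% is flagged and removed (the *earlier* interval is the
denominator). We flag exactly the two members of each violating pair: an
aberrant interval violates the rule against both of its neighbours, so the
chained violations around a premature/compensatory ectopic pair flag its
immediate neighbours as well — e.g. in
`c(0.8, 0.8, 0.48, 1.12, 0.8, 0.8)` intervals 2–5 are removed and the outer
beats survive. Flagging a fixed ±1 neighbourhood instead would remove the
entire series in that canonical example, so the narrower rule is used.
Removed intervals are spliced out, never interpolated. A recording losing
more than 50% of its intervals is rejected as unusable; at the pipeline level
such subjects are excluded with a reason code. On synthetic ectopic fixtures
the filter removes ≥ 95% of injected pairs (property-tested).

# Smoothness-priors detrending

The trend of a cleaned series *z* is
`τ = (I + λ² D₂ᵀ D₂)⁻¹ z`, with `D₂` the second-difference operator and
λ = 500 by default; the stationary residual is `z − τ`. The regularizer
enters as λ² per the standard smoothness-priors formulation. The system is
solved exactly with a sparse Cholesky factorization (`Matrix`); at N ≈ 400
this costs milliseconds. Straight lines lie in the penalty null space and are
reproduced exactly, the operator is linear, and `trend + residual`
reconstructs the input to machine precision — all asserted in the tests.

**Detrended-condition convention.** The detrended metric panel is computed on
the *zero-mean residual* by default (`restore_mean = FALSE`). Fourteen of the
sixteen metrics are translation-invariant, so the choice only matters for SI
and AI, whose phase angles and radii are measured from the origin. Two
observations drove the default. First, on mean-restored residuals the angle
`θ ≈ |ΔRR| / (2·meanRR)` is effectively linear in the successive difference,
and any stationary series balances its linear acceleration/deceleration sums
almost exactly — detrended SI/AI collapse to a few hundredths and are
insensitive to genuine successive-difference skewness. Second, on zero-mean
residuals the detrended SI/AI sit roughly an order of magnitude *above* their
raw counterparts and respond monotonically to the generator's asymmetry dial,
which is both the behaviour short-term HRV asymmetry studies report for
detrended data and a property the test suite asserts. The mean-restored mode
is retained as an option for comparability. Spectral metrics of the residual
are interpolated at the beat times of the original cleaned series (a
zero-mean residual has no meaningful cumulative sum).

# Conventional metrics

SDNN and RMSSD use sample statistics (ddof = 1) in milliseconds. Band powers
come from Welch's method: the tachogram is cubic-spline interpolated onto a
uniform 4 Hz grid over the cumulative beat times (linear interpolation is
config-exposed), segmented into 256-sample Hamming windows with 50% overlap,
mean-removed per segment (trend handling belongs to the detrending stage, so
no per-segment linear detrend), and transformed with a 1024-point FFT. Welch
averaging with these exact conventions is implemented directly on `stats::fft`
since no installed R package provides the segmented-periodogram estimator.
Band powers integrate the one-sided PSD by the trapezoidal rule over
LF = [0.04, 0.15) Hz and HF = [0.15, 0.40] Hz — the shared edge belongs to
HF — and are reported in ms². A series must span at least 128 s (two
segments at 4 Hz).

ApEn and SampEn use the field-standard parameters m = 2,
r = 0.2 × SD(series), Chebyshev distance; ApEn includes self-matches,
SampEn excludes them and draws both template sets from the first N − m
positions. Scaling r by the per-series SD makes SampEn invariant under affine
transforms. A series with no matches returns `+Inf` with a `degenerate`
flag rather than an error. Both implementations are verified to 1e−10
against O(N²)/O(N³) direct-definition oracles.

# Poincaré graphical metrics

The plot pairs each interval with its successor, `(RR_i, RR_{i+1})`;
points below the identity line are accelerations.

**Ellipse.** `SD1 = √(Var(ΔRR)/2)`, `SD2 = √(2 Var(RR) − Var(ΔRR)/2)`
(sample variances; a negative radicand is clipped to zero with a flag). Two
identities follow exactly and are asserted: `SD1² + SD2² = 2 SDNN²` and
`SD1 = SDSD/√2`.

**Asymmetry indices.** With A the accelerating points and O all off-identity
points, each index is `|100 · Σ_A w / Σ_O w − 50|` for a weight *w*: point
counts (PI), vertical distances `|y − x|` (GI), phase angles relative to the
identity line (SI), and sector areas `r² θ/2` (AI). Conventions:

* Points exactly on the identity line are excluded from numerator and
  denominator (the canonical Porta treatment).
* GI uses *linear* vertical distances by default; the classic
  squared-perpendicular-distance Guzik variant is available via
  `gi_mode = "squared"`. The perpendicular distance `|y − x|/√2` differs
  from the vertical one by a constant that cancels in the ratio, so that
  choice is observationally irrelevant and not configurable.
* The angle is computed in identity-rotated coordinates,
  `θ = atan2(|y − x|, x + y)`, mathematically equal to
  `|45° − atan2(y, x)|` but bit-symmetric under point mirroring; combined
  with the difference form `50 |Σ_A − Σ_D| / (Σ_A + Σ_D)` this makes a
  mirror-symmetric point set yield *exactly* zero for all four indices.
* AI's "total area" is the sum of per-point sector areas (the area-index
  literature's construction); a convex-hull total is not meaningful for a
  ratio that must equal 50% under symmetry.

**Grid metrics.** The plane is covered by one *square* bounding box over the
combined coordinate range (matching the square grids used for such plots;
per-axis boxes are config-exposed), split into n × n half-open cells with
far-edge points assigned to the last cell. GDR is the occupied-cell fraction;
GDE is the Shannon entropy of cell occupancy in *natural* log — for ~360
near-uniquely scattered beats GDE saturates towards ln(N) ≈ 5.9, the
magnitude reported for 5-minute recordings, which is inconsistent with log₂
or log₁₀. Both are averaged, unweighted, over all 101 integer resolutions
n = 100…200; per-resolution traces are retained. Binning is affine-invariant,
so uniform time-scaling changes nothing (property-tested).

# Statistics layer

* **Normality gate:** Shapiro–Wilk per group at α = 0.05; Student's t only
  when *both* groups pass (the conservative conjunction), otherwise
  Mann–Whitney, two-sided. Group summaries follow the decision
  (mean ± SD vs median (Q1, Q3)).
* **Cohen's d** always uses the pooled sample SD of the raw values, even when
  the gate chose Mann–Whitney, with the large-sample CI
  `d ± 1.96 √((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂)))`; CI coverage is verified by
  simulation (~95%).
* **ANCOVA:** `metric ~ group + age + menopause + pr + ki67` with the group
  coded 0/1; the group coefficient's t-test equals the Type-III test for a
  binary factor. Partial η² = SS_group/(SS_group + SS_residual), verified
  numerically to equal the squared partial correlation. Collinear covariates
  raise an error naming the offending columns.
* **ROC:** AUC by the midrank (Mann–Whitney) formulation, tie-corrected;
  auto-orientation reports the direction actually used, since which class
  counts as "positive" at a given threshold is a reporting convention that
  must be recorded, not guessed.
* **Cross-validated ROC:** stratified 10-fold; a univariable logistic score
  fit per training fold and applied to its validation fold; pooled
  validation scores give the CV-AUC and the Youden-optimal
  sensitivity/specificity. Any monotone per-fold scoring model yields the
  same pooled ranking, so logistic regression is a benign, explicit choice.
  Fold assignment is seeded and recorded.
* **No multiple-testing correction** is applied; the report metadata states
  this. The panel's metrics are geometrically interdependent, so FDR-style
  corrections treat them as more independent than they are; uncorrected
  p-values with effect sizes and CIs are reported instead.
* `build_report` runs ANCOVA only for metrics with unadjusted p < α, and ROC
  for those metrics (capped at three) or, failing any, the smallest-p metric.

# Synthetic data: what it emulates and what it does not

`generate_rri` composes
`RR_i = meanRR + LF sinusoid + HF sinusoid + slow trend + jitter`, with the
sinusoids evaluated at nominal beat times. Defaults are the study conditions:
mean RR 0.82 s (≈ 73 bpm), 365 beats (≈ 5 min), LF at 0.10 Hz and HF at
0.25 Hz with 15 ms amplitude each (~110 ms² band power), a 20 ms slow trend
at 0.01 Hz (below the LF band, the component detrending must remove), and
17 ms AR(1) jitter (lag-1 correlation 0.5) giving SDNN ≈ 27 ms and
RMSSD ≈ 20 ms — the magnitudes typical of resting breast-cancer cohorts.

Heart-rate asymmetry is injected by skewing the jitter innovations: a
two-sided exponential with unequal rates, `P(positive) = (1 + s)/2` and
branch means chosen so the innovation stays zero-mean at fixed variance.
Positive `s` makes decelerations more frequent but smaller and accelerations
rarer but larger, raising PI and — through the origin-referenced geometry of
the detrended condition — SI and AI monotonically, which is how a graded
group effect is produced without editing points post hoc. Ectopic artifacts
are premature/compensatory pairs (×0.6 then ×1.4), guaranteed to violate the
20% rule on a clean baseline, with positions recorded so QC recall is
measurable.

`synthesize_ecg` is a *fixture generator*, not a morphology model: a Ricker
(biphasic, ~80 ms) QRS template at each cumulative beat time, an optional
Gaussian T-wave 250 ms after each R, a sub-0.5 Hz baseline-wander sinusoid
and white noise, with the true R-sample indices returned for auditing. It has
no P waves, ST segments, or arrhythmias, so detector tests on it demonstrate
correctness of the chain's logic, not clinical-grade robustness.

`generate_cohort` draws 142 + 76 subjects by default, with per-group age
(51.6 ± 10.2 vs 48.9 ± 9.7 years) and menopause/PR/Ki-67 prevalences
(55.6/48.6/78.7% vs 32.9/63.2/52.6%) matching a breast-cancer axillary-staging
population; covariates are independent of the metrics by construction — group
effects enter only through the generator dials. `simulate_metric_cohort`
generates metric *values* directly (unit-variance Gaussians with specified
standardized shifts and an optional menopause-driven confounding term); it
exists so the statistics layer can be calibrated with hundreds of replicates
at negligible cost, which signal-level simulation cannot provide.

Passing tests on these generators show the pipeline's algorithms are correct
and its statistics calibrated under the stated signal model; they cannot show
robustness to real-world non-idealities (arrhythmia, electrode artifacts,
respiration-coupled nonstationarity) that the model does not contain.

# Problem sizes and numerical tolerances

The test suite verifies metric implementations against brute-force oracles on
50 random series of length 20–100 (tolerance 1e−10); detector accuracy on
20 seeds × 2 noise conditions of 5-minute 400 Hz ECGs (recall/precision
≥ 0.99 within ±5 ms); detrending exactness at 1e−9/1e−12; statistical
calibration on 500 zero-effect replicates of a 142/76 metric-level cohort
(rejection 5% ± 2%), 150 permuted-label CV runs (mean CV-AUC 0.50 ± 0.02),
and 500 effect-recovery replicates at d = 0.4; and a full 218-subject
signal-level cohort run, executed twice to assert byte-identical outputs
under a fixed seed. These sizes were chosen so Monte-Carlo standard errors
sit comfortably inside the asserted bands.

Degenerate inputs are contracts, not crashes: constant series give zero
SDNN/RMSSD/SD1/SD2 and flagged-undefined asymmetry ratios; a zero coordinate
range gives GDR = 1/n², GDE = 0 by convention; zero-variance logistic fits
in perfectly separated CV folds are tolerated (`suppressWarnings`) because
only the score ranking matters.

# Known limitations

* The ECG model is deliberately minimal; detector performance on real
  recordings with muscle noise, electrode motion or arrhythmia is untested
  here.
* The QC filter discards rather than interpolates; series with very high
  ectopic burden lose power in the frequency domain.
* SI and AI depend on the detrended-condition convention (zero-mean vs
  mean-restored); both modes are provided, and cross-study comparisons must
  match conventions.
* The CV sensitivity/specificity operating point (Youden on pooled
  validation scores) is one of several defensible conventions; reported
  operating points are only comparable under the same convention, which is
  why the orientation and seed are recorded in every ROC result.
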