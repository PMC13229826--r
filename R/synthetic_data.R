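#' Parameters for the synthetic RR-interval generator
#'
#' The generator composes a tachogram additively from a mean level, an LF
#' oscillation (baroreflex band, default 0.10 Hz), an HF oscillation
#' (respiratory band, default 0.25 Hz), a slow non-stationary trend (default
#' 0.01 Hz, below the LF band), and a stationary jitter process whose
#' successive-difference distribution can be skewed to induce heart-rate
#' asymmetry.
#'
#' Defaults emulate a 5-minute resting recording of an adult at a mean heart
#' rate near 73 bpm, with amplitudes chosen so that SDNN, RMSSD and the LF/HF
#' band powers fall in the range typical of short-term resting HRV
#' (SDNN ~ 25-30 ms, LF and HF ~ 100-250 ms^2).
#'
#' @param mean_rr Mean RR interval in seconds, in (0.3, 2.0).
#' @param n_beats Number of intervals to generate.
#' @param lf_amp,lf_freq Amplitude (s) and frequency (Hz) of the LF sinusoid.
#' @param hf_amp,hf_freq Amplitude (s) and frequency (Hz) of the HF sinusoid.
#' @param trend_amp,trend_freq Amplitude (s) and frequency (Hz) of the slow
#'   trend component; `trend_freq` should sit below the LF band.
#' @param jitter_sd Marginal standard deviation (s) of the stationary jitter.
#' @param asym_skew Asymmetry dial in \[-1, 1\]. 0 gives a symmetric
#'   successive-difference distribution; positive values make decelerations
#'   (successor longer) more frequent but smaller and accelerations rarer but
#'   larger, raising the raw asymmetry indices.
#' @param jitter_ar Lag-1 autocorrelation of the jitter process in \[0, 1).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `rri_gen_params`.
#' @export
rri_gen_params <- function(mean_rr = 0.82, n_beats = 365,
                           lf_amp = 0.015, lf_freq = 0.10,
                           hf_amp = 0.015, hf_freq = 0.25,
                           trend_amp = 0.020, trend_freq = 0.01,
                           jitter_sd = 0.017, asym_skew = 0,
                           jitter_ar = 0.5, seed = 1L) {
  stopifnot(mean_rr > 0.3, mean_rr < 2.0, n_beats >= 1,
            lf_amp >= 0, hf_amp >= 0, trend_amp >= 0, jitter_sd >= 0,
            asym_skew >= -1, asym_skew <= 1,
            jitter_ar >= 0, jitter_ar < 1)
  structure(as.list(environment()), class = "rri_gen_params")
}

# Zero-mean two-sided exponential innovations with unequal rates.
# skew in [-1, 1]; P(positive) = (1 + skew)/2; positive/negative scales are
# chosen so the mean is exactly zero and the variance equals sd^2.
rskew2exp <- function(n, sd, skew) {
  if (sd == 0) return(numeric(n))
  p <- (1 + skew) / 2
  p <- min(max(p, 1e-6), 1 - 1e-6)
  cc <- sd / sqrt(2 * p * (1 - p))
  a <- cc * (1 - p)   # mean of positive branch
  b <- cc * p         # mean of negative branch
  pos <- stats::runif(n) < p
  out <- numeric(n)
  out[pos] <- stats::rexp(sum(pos), rate = 1 / a)
  out[!pos] <- -stats::rexp(sum(!pos), rate = 1 / b)
  out
}

#' Generate a synthetic RR-interval series
#'
#' @param params An [rri_gen_params()] object.
#' @return An [rri_series()] with provenance `"raw"`.
#' @details The series is
#'   `RR_i = mean_rr + LF + HF + trend + jitter_i`, with the sinusoids
#'   evaluated at nominal beat times `i * mean_rr` and the jitter an AR(1)
#'   process driven by zero-mean two-sided exponential innovations whose
#'   rates are unequal when `asym_skew != 0`. Parameters that would produce
#'   a non-positive interval are rejected with an error.
#' @export
generate_rri <- function(params) {
  stopifnot(inherits(params, "rri_gen_params"))
  p <- params
  withr_seed <- set_local_seed(p$seed)
  on.exit(withr_seed())
  i <- seq_len(p$n_beats)
  t <- i * p$mean_rr
  rr <- p$mean_rr +
    p$lf_amp * sin(2 * pi * p$lf_freq * t) +
    p$hf_amp * sin(2 * pi * p$hf_freq * t) +
    p$trend_amp * sin(2 * pi * p$trend_freq * t)
  if (p$jitter_sd > 0) {
    rho <- p$jitter_ar
    innov_sd <- p$jitter_sd * sqrt(1 - rho^2)
    e <- rskew2exp(p$n_beats, innov_sd, p$asym_skew)
    j <- numeric(p$n_beats)
    j[1] <- e[1] / sqrt(1 - rho^2)
    for (k in seq_len(p$n_beats - 1L)) j[k + 1L] <- rho * j[k] + e[k + 1L]
    rr <- rr + j
  }
  if (any(rr <= 0)) {
    stop("generate_rri(): parameter combination produced a non-positive ",
         "interval; reduce amplitudes or jitter_sd")
  }
  rri_series(rr, provenance = "raw")
}

# Seed handling: save and restore .Random.seed so generators are
# deterministic without clobbering the caller's RNG stream.
set_local_seed <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Inject ectopic-beat artifacts into an RR series
#'
#' Each eligible beat is independently selected with probability
#' `ectopic_rate` and replaced, together with its successor, by a
#' premature/compensatory pair: the selected interval is multiplied by 0.6
#' and the next by 1.4. Selected positions are returned so that
#' quality-control recall can be measured.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param ectopic_rate Probability in \[0, 0.2\] of a beat starting a pair.
#' @param seed Integer seed.
#' @return An [rri_series()] with attribute `ectopic_positions` (indices of
#'   the premature interval of each injected pair).
#' @export
inject_artifacts <- function(rri, ectopic_rate, seed = 1L) {
  stopifnot(ectopic_rate >= 0, ectopic_rate <= 0.2)
  x <- rri_values(rri)
  n <- length(x)
  restore <- set_local_seed(seed)
  on.exit(restore())
  pos <- integer(0)
  if (ectopic_rate > 0 && n >= 2) {
    u <- stats::runif(n - 1L)
    cand <- which(u < ectopic_rate)
    # drop overlapping pairs: keep a candidate only if it does not touch the
    # previously kept pair
    last <- -2L
    for (i in cand) {
      if (i > last + 1L) {
        pos <- c(pos, i)
        last <- i
      }
    }
    for (i in pos) {
      x[i] <- 0.6 * x[i]
      x[i + 1L] <- 1.4 * x[i + 1L]
    }
  }
  out <- rri_series(x, provenance = "raw",
                    id = if (inherits(rri, "rri_series")) rri$id else NULL)
  attr(out, "ectopic_positions") <- pos
  out
}

#' Synthesize a single-lead ECG trace from an RR series
#'
#' Places a narrow biphasic QRS template (a Ricker wavelet of total width
#' about 80 ms) at each cumulative beat time, optionally adds a low-amplitude
#' T-wave bump 250 ms after each R peak, a sub-0.5 Hz baseline-wander
#' sinusoid, and white Gaussian noise. The true R-peak sample indices are
#' returned alongside the trace so detector accuracy can be audited.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param fs Sampling frequency in Hz (>= 100).
#' @param qrs_amp QRS amplitude in mV.
#' @param noise_sd White-noise standard deviation in mV.
#' @param wander_amp Baseline-wander amplitude in mV.
#' @param wander_freq Baseline-wander frequency in Hz (< 0.5).
#' @param twave_amp T-wave amplitude in mV (0 disables the T wave).
#' @param seed Integer seed for the noise.
#' @return An [ecg_record()] with attribute `true_rpeaks` (0-based sample
#'   indices of the template centers).
#' @export
synthesize_ecg <- function(rri, fs = 400, qrs_amp = 1.0, noise_sd = 0,
                           wander_amp = 0, wander_freq = 0.3,
                           twave_amp = 0, seed = 1L) {
  stopifnot(fs >= 100, wander_freq < 0.5, wander_freq > 0)
  x <- rri_values(rri)
  beat_times <- cumsum(c(0.5, x))  # first R at 0.5 s, then one per interval
  dur <- beat_times[length(beat_times)] + 0.5
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  sig <- numeric(n)
  # Ricker (mexican-hat) QRS template: biphasic, ~80 ms total support
  sigma <- 0.012
  half <- round(0.04 * fs)
  k <- seq(-half, half)
  tau <- k / fs
  template <- qrs_amp * (1 - (tau / sigma)^2) * exp(-tau^2 / (2 * sigma^2))
  r_idx <- round(beat_times * fs)  # 0-based
  for (ri in r_idx) {
    lo <- ri - half
    hi <- ri + half
    sel <- which(lo + k >= 0 & lo + k < n) # guard both edges
    idx <- (ri + k[sel]) + 1L
    sig[idx] <- sig[idx] + template[sel]
  }
  if (twave_amp > 0) {
    tsig <- 0.05
    thalf <- round(0.12 * fs)
    tk <- seq(-thalf, thalf)
    ttau <- tk / fs
    ttemplate <- twave_amp * exp(-ttau^2 / (2 * tsig^2))
    for (ri in r_idx) {
      ci <- ri + round(0.25 * fs)
      sel <- which(ci + tk >= 0 & ci + tk < n)
      idx <- (ci + tk[sel]) + 1L
      sig[idx] <- sig[idx] + ttemplate[sel]
    }
  }
  if (wander_amp > 0) sig <- sig + wander_amp * sin(2 * pi * wander_freq * tt)
  if (noise_sd > 0) {
    restore <- set_local_seed(seed)
    on.exit(restore())
    sig <- sig + stats::rnorm(n, sd = noise_sd)
  }
  out <- ecg_record(sig, fs)
  attr(out, "true_rpeaks") <- r_idx
  out
}

#' Parameters for the two-group synthetic cohort generator
#'
#' Group sizes and covariate prevalences default to a 218-subject cohort of
#' 142 positive and 76 negative subjects, with per-group age distributions
#' and menopause / progesterone-receptor / Ki-67 prevalences typical of a
#' breast-cancer axillary-staging population.
#'
#' @param n_pos,n_neg Group sizes (>= 2 each).
#' @param ai_effect Shift of `asym_skew` applied to the positive group
#'   (dimensionless; raises its heart-rate asymmetry).
#' @param complexity_effect Fractional reduction of `jitter_sd` and
#'   `trend_amp` in the positive group, in \[0, 1).
#' @param age_mean,age_sd Length-2 vectors (positive, negative group).
#' @param menopause_prev,pr_prev,ki67_prev Length-2 prevalence vectors
#'   (positive, negative group), each in \[0, 1\].
#' @param base Baseline [rri_gen_params()] shared by both groups.
#' @param seed Integer seed.
#' @return A list of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_pos = 142, n_neg = 76,
                              ai_effect = 0, complexity_effect = 0,
                              age_mean = c(51.6, 48.9), age_sd = c(10.2, 9.7),
                              menopause_prev = c(0.556, 0.329),
                              pr_prev = c(0.486, 0.632),
                              ki67_prev = c(0.787, 0.526),
                              base = rri_gen_params(), seed = 1L) {
  stopifnot(n_pos >= 2, n_neg >= 2,
            all(menopause_prev >= 0 & menopause_prev <= 1),
            all(pr_prev >= 0 & pr_prev <= 1),
            all(ki67_prev >= 0 & ki67_prev <= 1),
            complexity_effect >= 0, complexity_effect < 1,
            inherits(base, "rri_gen_params"))
  structure(as.list(environment()), class = "cohort_gen_params")
}

#' Generate a synthetic two-group cohort of RR series with covariates
#'
#' @param params A [cohort_gen_params()] object.
#' @return A list with elements `subjects` (list of [rri_series()]) and
#'   `covariates` (data frame with `subject_id`, `group` in
#'   \{"positive","negative"\}, `age`, `menopause`, `pr`, `ki67`).
#'   Reproducible under `params$seed`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_gen_params"))
  p <- params
  restore <- set_local_seed(p$seed)
  on.exit(restore())
  n_all <- p$n_pos + p$n_neg
  group <- rep(c("positive", "negative"), c(p$n_pos, p$n_neg))
  gi <- ifelse(group == "positive", 1L, 2L)
  age <- stats::rnorm(n_all, p$age_mean[gi], p$age_sd[gi])
  menopause <- as.integer(stats::runif(n_all) < p$menopause_prev[gi])
  pr <- as.integer(stats::runif(n_all) < p$pr_prev[gi])
  ki67 <- as.integer(stats::runif(n_all) < p$ki67_prev[gi])
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_all)
  subjects <- vector("list", n_all)
  ids <- sprintf("S%03d", seq_len(n_all))
  for (s in seq_len(n_all)) {
    gp <- p$base
    if (group[s] == "positive") {
      gp$asym_skew <- gp$asym_skew + p$ai_effect
      gp$jitter_sd <- gp$jitter_sd * (1 - p$complexity_effect)
      gp$trend_amp <- gp$trend_amp * (1 - p$complexity_effect)
    }
    gp$seed <- subject_seeds[s]
    rr <- generate_rri(gp)
    rr$id <- ids[s]
    subjects[[s]] <- rr
  }
  list(subjects = subjects,
       covariates = data.frame(subject_id = ids, group = group, age = age,
                               menopause = menopause, pr = pr, ki67 = ki67,
                               stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Writes one RRI text file per subject (one interval per line, seconds) and
#' a manifest CSV with header
#' `subject_id,path,group,age,menopause,pr,ki67`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- cohort$covariates
  paths <- file.path(dir, paste0(cov$subject_id, ".rri.txt"))
  for (s in seq_along(cohort$subjects)) {
    writeLines(format_rri(cohort$subjects[[s]]$intervals), paths[s])
  }
  manifest <- cbind(cov[, "subject_id", drop = FALSE],
                    path = basename(paths),
                    cov[, c("group", "age", "menopause", "pr", "ki67")])
  mpath <- file.path(dir, "cohort.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

format_rri <- function(x) sprintf("%.9f", x)

#' Simulate a metric-level cohort table for the statistics layer
#'
#' Generates per-subject metric values directly (bypassing signal synthesis)
#' so the statistical layer can be calibrated with many replicates cheaply.
#' Metrics are unit-variance Gaussian within group; `effects` shifts the
#' positive group's mean by the stated standardized amount. `confounding`
#' adds a covariate-driven component: the named metric gains
#' `confounding * menopause` with no direct group effect, so any marginal
#' group difference is carried entirely by the differing menopause
#' prevalence between groups.
#'
#' @param n_pos,n_neg Group sizes.
#' @param effects Named numeric vector of standardized group mean shifts,
#'   e.g. `c(ai_detrended = 0.4)`. Unnamed metrics default to zero effect.
#' @param metrics Character vector of metric column names to simulate.
#' @param confounding Single named numeric value (or NULL): coefficient of
#'   the menopause covariate on that metric.
#' @param seed Integer seed.
#' @return A data frame: `subject_id`, `group`, covariates, one column per
#'   metric.
#' @export
simulate_metric_cohort <- function(n_pos = 142, n_neg = 76,
                                   effects = c(ai_detrended = 0),
                                   metrics = names(effects),
                                   confounding = NULL, seed = 1L) {
  restore <- set_local_seed(seed)
  on.exit(restore())
  n_all <- n_pos + n_neg
  group <- rep(c("positive", "negative"), c(n_pos, n_neg))
  gi <- ifelse(group == "positive", 1L, 2L)
  cov <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_all)),
    group = group,
    age = stats::rnorm(n_all, c(51.6, 48.9)[gi], c(10.2, 9.7)[gi]),
    menopause = as.integer(stats::runif(n_all) < c(0.556, 0.329)[gi]),
    pr = as.integer(stats::runif(n_all) < c(0.486, 0.632)[gi]),
    ki67 = as.integer(stats::runif(n_all) < c(0.787, 0.526)[gi]),
    stringsAsFactors = FALSE)
  for (m in metrics) {
    eff <- if (!is.null(names(effects)) && m %in% names(effects)) effects[[m]] else 0
    v <- stats::rnorm(n_all) + ifelse(group == "positive", eff, 0)
    if (!is.null(confounding) && m %in% names(confounding)) {
      v <- v + confounding[[m]] * cov$menopause
    }
    cov[[m]] <- v
  }
  cov
}
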