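test_that("degenerate parameters give an exactly constant series", {
  p <- rri_gen_params(mean_rr = 0.8, n_beats = 10, lf_amp = 0, hf_amp = 0,
                      trend_amp = 0, jitter_sd = 0)
  rr <- generate_rri(p)
  expect_identical(rr$intervals, rep(0.8, 10))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_rri(rri_gen_params(seed = 11))
  b <- generate_rri(rri_gen_params(seed = 11))
  c <- generate_rri(rri_gen_params(seed = 12))
  expect_identical(a$intervals, b$intervals)
  expect_false(identical(a$intervals, c$intervals))
})

test_that("all generated intervals are positive and mean is near mean_rr", {
  for (s in 1:5) {
    rr <- generate_rri(rri_gen_params(seed = s))
    expect_true(all(rr$intervals > 0))
    expect_lt(abs(mean(rr$intervals) - 0.82), 0.02)
  }
})

test_that("HF-dominant parameters put spectral power in the HF band", {
  p <- rri_gen_params(hf_amp = 0.03, lf_amp = 0, trend_amp = 0,
                      jitter_sd = 0.001, n_beats = 400, seed = 2)
  bp <- welch_band_powers(generate_rri(p))
  expect_gt(bp$hf / (bp$lf + bp$hf), 0.95)
})

test_that("a symmetric generator yields small raw asymmetry indices", {
  vals <- t(vapply(1:20, function(s) {
    rr <- generate_rri(rri_gen_params(n_beats = 3000, asym_skew = 0, seed = s))
    unlist(asymmetry_metrics(rr)[c("pi", "gi", "si", "ai")])
  }, numeric(4)))
  # each index < 2.0 for the large majority of seeds, and small on average
  expect_gte(mean(vals < 2.0), 0.95)
  expect_true(all(colMeans(vals) < 1.0))
})

test_that("positive asym_skew raises asymmetry monotonically", {
  mean_ai <- vapply(c(0, 0.4, 0.8), function(eff) {
    ais <- vapply(1:15, function(s) {
      rr <- generate_rri(rri_gen_params(n_beats = 1000, asym_skew = eff,
                                        seed = 100 + s))
      d <- smoothness_priors_detrend(rr)
      asymmetry_metrics(detrended_values(d))$ai
    }, numeric(1))
    mean(ais)
  }, numeric(1))
  expect_true(all(diff(mean_ai) > 0))
})

test_that("artifact injection is the identity at rate zero", {
  rr <- generate_rri(rri_gen_params(seed = 4))
  out <- inject_artifacts(rr, 0, seed = 1)
  expect_identical(out$intervals, rr$intervals)
  expect_length(attr(out, "ectopic_positions"), 0)
})

test_that("artifact injection count tracks the rate and positions are recorded", {
  rr <- rri_series(rep(0.8, 300))
  out <- inject_artifacts(rr, 0.05, seed = 6)
  pos <- attr(out, "ectopic_positions")
  expect_gt(length(pos), 5)
  expect_lt(length(pos), 30)
  # injected pair on a 0.8 s baseline: 0.48 then 1.12, both violating the
  # 20% adjacent-change rule relative to the 0.8 s neighbours
  expect_equal(out$intervals[pos], rep(0.48, length(pos)))
  expect_equal(out$intervals[pos + 1], rep(1.12, length(pos)))
  expect_true(all(abs(diff(out$intervals))[pos - 1] / 0.8 > 0.2))
})

test_that("noiseless ECG synthesis places the template apex at the true R time", {
  rr <- rri_series(rep(0.8, 20))
  ecg <- synthesize_ecg(rr, fs = 400, noise_sd = 0, wander_amp = 0)
  truth <- attr(ecg, "true_rpeaks")
  for (t in truth[2:(length(truth) - 1)]) {
    win <- (t - 40):(t + 40) + 1  # 0-based truth -> 1-based samples
    expect_equal(win[which.max(ecg$samples[win])] - 1, t)
  }
})

test_that("a 300 s recording at mean RR 0.82 contains about 366 beats", {
  p <- rri_gen_params(mean_rr = 0.82, n_beats = 366, lf_amp = 0, hf_amp = 0,
                      trend_amp = 0, jitter_sd = 0)
  ecg <- synthesize_ecg(generate_rri(p), fs = 400)
  expect_equal(length(attr(ecg, "true_rpeaks")), 367)  # n_beats + 1 peaks
  expect_equal(length(ecg$samples) / 400, 366 * 0.82 + 1, tolerance = 0.01)
})

test_that("default cohort matches the expected sizes and covariate structure", {
  cohort <- generate_cohort(cohort_gen_params(seed = 8))
  cov <- cohort$covariates
  expect_equal(nrow(cov), 218)
  expect_equal(sum(cov$group == "positive"), 142)
  expect_equal(sum(cov$group == "negative"), 76)
  expect_length(cohort$subjects, 218)
  men_pos <- mean(cov$menopause[cov$group == "positive"])
  men_neg <- mean(cov$menopause[cov$group == "negative"])
  expect_lt(abs(men_pos - 0.556), 0.12)
  expect_lt(abs(men_neg - 0.329), 0.13)
  expect_gt(men_pos, men_neg)
})

test_that("cohorts are bit-identical under a fixed seed", {
  a <- generate_cohort(cohort_gen_params(n_pos = 5, n_neg = 4, seed = 3))
  b <- generate_cohort(cohort_gen_params(n_pos = 5, n_neg = 4, seed = 3))
  expect_identical(a, b)
})

test_that("cohort writing round-trips through the manifest", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_gen_params(
    n_pos = 3, n_neg = 3, seed = 5,
    base = rri_gen_params(n_beats = 50)))
  mpath <- write_cohort(cohort, dir)
  man <- read.csv(mpath)
  expect_named(man, c("subject_id", "path", "group", "age", "menopause",
                      "pr", "ki67"))
  rr <- read_rri(file.path(dir, man$path[1]))
  expect_equal(rr$intervals, cohort$subjects[[1]]$intervals, tolerance = 1e-8)
})
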