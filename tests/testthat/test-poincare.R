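test_that("poincare point counts partition the point set", {
  pp <- poincare_points(c(0.8, 0.9, 0.9, 0.7))
  expect_equal(length(pp$x), 3)
  expect_equal(pp$n_accel + pp$n_decel + pp$n_online, 3)
  expect_equal(pp$n_online, 1)
})

test_that("ellipse metrics: alternating, constant, and identity cases", {
  alt <- rep(c(0.8, 0.9), 10)
  em <- ellipse_metrics(alt)
  expect_lt(em$sd2, 2)           # nearly zero along the identity line
  expect_gt(em$sd1, 60)          # ~70.7 ms up to the ddof factor
  expect_gt(em$sd1 / em$sd2, 10)
  emc <- ellipse_metrics(rep(0.8, 10))
  expect_equal(emc$sd1, 0)
  expect_equal(emc$sd2, 0)
  expect_true(is.na(emc$ratio))
})

test_that("SD1^2 + SD2^2 = 2 SDNN^2 and SD1 = SDSD/sqrt(2)", {
  for (s in 1:10) {
    x <- random_series(60, s)
    em <- ellipse_metrics(x)
    expect_equal(em$sd1^2 + em$sd2^2, 2 * sdnn(x)^2, tolerance = 1e-9)
    expect_equal(em$sd1, sd(diff(x)) * 1000 / sqrt(2), tolerance = 1e-9)
  }
})

test_that("mirror-symmetric point sets give exactly zero asymmetry", {
  am <- asymmetry_metrics(c(0.8, 0.9, 0.8, 0.9, 0.8))
  expect_identical(am$pi, 0)
  expect_identical(am$gi, 0)
  expect_identical(am$si, 0)
  expect_identical(am$ai, 0)
})

test_that("asymmetry indices match the worked example", {
  am <- asymmetry_metrics(c(0.8, 1.0, 0.9, 0.7))
  expect_equal(am$pi, abs(100 * 2 / 3 - 50), tolerance = 1e-12)
  expect_equal(am$gi, 10, tolerance = 1e-12)
})

test_that("a constant series has undefined asymmetry, flagged not thrown", {
  am <- asymmetry_metrics(rep(0.8, 10))
  expect_true(am$degenerate)
  expect_true(is.na(am$pi))
})

test_that("swapping accelerations and decelerations leaves |X-50| unchanged", {
  for (s in 1:10) {
    x <- random_series(40, 100 + s)
    am1 <- asymmetry_metrics(x)
    am2 <- asymmetry_metrics(rev(x))  # reverses every (x,y) to (y,x)
    for (k in c("pi", "gi", "si", "ai")) {
      expect_equal(am1[[k]], am2[[k]], tolerance = 1e-9)
    }
  }
})

test_that("all four asymmetry indices are invariant to uniform time scaling", {
  x <- random_series(80, 7)
  a1 <- asymmetry_metrics(x)
  a2 <- asymmetry_metrics(1.7 * x)
  for (k in c("pi", "gi", "si", "ai")) {
    expect_equal(a1[[k]], a2[[k]], tolerance = 1e-9)
  }
})

test_that("the squared-distance Guzik variant differs but stays in range", {
  x <- random_series(80, 8)
  g1 <- asymmetry_metrics(x)$gi
  g2 <- asymmetry_metrics(x, gi_mode = "squared")$gi
  expect_true(g2 >= 0 && g2 <= 50)
  expect_false(isTRUE(all.equal(g1, g2)))
})

test_that("grid occupancy matches closed-form cases", {
  # all points identical
  g <- grid_metrics_at(rep(0.8, 10), n = 7)
  expect_equal(g$gdr, 1 / 49)
  expect_equal(g$gde, 0)
  expect_true(g$degenerate)
  # four points, one per quadrant of the box, n = 2
  g4 <- grid_metrics_at(c(0.6, 0.61, 1.0, 1.01, 0.62), n = 2)
  expect_equal(g4$gdr, 1.0)
  expect_equal(g4$gde, log(4), tolerance = 1e-12)
})

test_that("grid metrics match the brute-force occupancy oracle", {
  for (s in 1:10) {
    x <- random_series(20, 300 + s)
    for (n in c(3, 5, 12)) {
      g <- grid_metrics_at(x, n)
      o <- o_grid_at(x, n)
      expect_equal(g$gdr, unname(o["gdr"]), tolerance = 1e-12)
      expect_equal(g$gde, unname(o["gde"]), tolerance = 1e-12)
    }
  }
})

test_that("multi-resolution averaging covers 101 resolutions and is scale invariant", {
  rr <- generate_rri(rri_gen_params(seed = 25))
  gm <- grid_metrics(rr)
  expect_equal(nrow(gm$trace), 101)
  expect_equal(gm$gdr, mean(gm$trace$gdr_n))
  expect_equal(gm$gde, mean(gm$trace$gde_n))
  gm2 <- grid_metrics(2 * rr$intervals)
  expect_equal(gm$gdr, gm2$gdr, tolerance = 1e-12)
  expect_equal(gm$gde, gm2$gde, tolerance = 1e-12)
})

test_that("a 5-minute series lands in the expected GDR/GDE range", {
  rr <- generate_rri(rri_gen_params(n_beats = 365, seed = 26))
  gm <- grid_metrics(rr)
  n_pts <- length(rr$intervals) - 1
  expect_gt(gm$gdr, 0.010)
  expect_lt(gm$gdr, 0.025)
  expect_gt(gm$gde, 5.4)
  expect_lte(gm$gde, log(n_pts))
})

test_that("GDE saturates at ln(N) and occupancy bounds hold at every n", {
  x <- random_series(30, 55)
  n_pts <- length(x) - 1
  gm <- grid_metrics(x, 10, 60)
  expect_true(all(gm$trace$gde_n <= log(n_pts) + 1e-12))
  expect_true(all(gm$trace$gdr_n * gm$trace$n^2 <= n_pts + 1e-9))
})

test_that("the metric panel returns all 16 named metrics", {
  rr <- generate_rri(rri_gen_params(seed = 27))
  m <- metric_panel(qc_filter(rr))
  expect_named(m, c("sdnn", "rmssd", "lf", "hf", "lf_hf", "apen", "sampen",
                    "sd1", "sd2", "sd1_sd2", "si", "pi", "gi", "ai",
                    "gdr", "gde"))
  expect_false(anyNA(m))
})
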