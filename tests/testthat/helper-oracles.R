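# Independent brute-force oracles, written from the metric definitions with
# plain loops. They deliberately share no code with the package internals.

o_sdnn <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1)) * 1000
}

o_rmssd <- function(x) {
  d <- x[-1] - x[-length(x)]
  sqrt(sum(d^2) / length(d)) * 1000
}

o_sd1sd2 <- function(x) {
  d <- x[-1] - x[-length(x)]
  vd <- sum((d - mean(d))^2) / (length(d) - 1)
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  c(sd1 = sqrt(vd / 2) * 1000, sd2 = sqrt(max(2 * vx - vd / 2, 0)) * 1000)
}

o_asym <- function(x) {
  cnt_a <- 0; cnt_o <- 0
  dist_a <- 0; dist_o <- 0
  ang_a <- 0; ang_o <- 0
  area_a <- 0; area_o <- 0
  for (i in seq_len(length(x) - 1)) {
    xi <- x[i]; yi <- x[i + 1]
    if (yi == xi) next
    d <- abs(yi - xi)
    th_deg <- abs(45 - atan2(yi, xi) * 180 / pi)
    s <- (xi^2 + yi^2) * (th_deg * pi / 180) / 2
    cnt_o <- cnt_o + 1; dist_o <- dist_o + d
    ang_o <- ang_o + th_deg; area_o <- area_o + s
    if (yi < xi) {
      cnt_a <- cnt_a + 1; dist_a <- dist_a + d
      ang_a <- ang_a + th_deg; area_a <- area_a + s
    }
  }
  if (cnt_o == 0) return(c(pi = NA, gi = NA, si = NA, ai = NA))
  c(pi = abs(100 * cnt_a / cnt_o - 50),
    gi = abs(100 * dist_a / dist_o - 50),
    si = abs(100 * ang_a / ang_o - 50),
    ai = abs(100 * area_a / area_o - 50))
}

o_grid_at <- function(x, n) {
  px <- x[-length(x)]; py <- x[-1]
  lo <- min(c(px, py)); hi <- max(c(px, py))
  if (hi == lo) return(c(gdr = 1 / n^2, gde = 0))
  counts <- matrix(0L, n, n)
  w <- (hi - lo) / n
  for (i in seq_along(px)) {
    cx <- min(floor((px[i] - lo) / w), n - 1) + 1
    cy <- min(floor((py[i] - lo) / w), n - 1) + 1
    counts[cx, cy] <- counts[cx, cy] + 1L
  }
  occ <- counts[counts > 0]
  p <- occ / sum(occ)
  c(gdr = length(occ) / n^2, gde = -sum(p * log(p)))
}

o_apen <- function(x, m = 2, rf = 0.2) {
  r <- rf * sd(x)
  phi <- function(mm) {
    nn <- length(x) - mm + 1
    total <- 0
    for (i in 1:nn) {
      cnt <- 0
      for (j in 1:nn) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / nn)
    }
    total / nn
  }
  phi(m) - phi(m + 1)
}

o_sampen <- function(x, m = 2, rf = 0.2) {
  r <- rf * sd(x)
  n <- length(x)
  np <- n - m
  A <- 0; B <- 0
  for (i in 1:(np - 1)) {
    for (j in (i + 1):np) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        dm1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (dm1 <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

o_auc <- function(values, labels, positive = "positive") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Squared partial correlation of metric with group given covariates,
# via explicit residualization.
o_partial_eta <- function(table, metric, covariates, positive = "positive") {
  g <- as.integer(table$group == positive)
  Xc <- as.matrix(table[, covariates])
  res_m <- residuals(lm(table[[metric]] ~ Xc))
  res_g <- residuals(lm(g ~ Xc))
  cor(res_m, res_g)^2
}

# Detection accuracy of a detected index set against truth (sample indices)
rpeak_accuracy <- function(detected, truth, tol) {
  if (!length(detected)) return(c(recall = 0, precision = NA))
  rec <- mean(vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1)))
  prec <- mean(vapply(detected, function(d) any(abs(truth - d) <= tol), logical(1)))
  c(recall = rec, precision = prec)
}

# Small random RR-like series for oracle-equivalence sweeps
random_series <- function(n, seed) {
  set.seed(seed)
  0.8 + rnorm(n, 0, 0.05)
}
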