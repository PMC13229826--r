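#' Poincare plot point set
#'
#' Successive-interval pairs `(x_i, y_i) = (RR_i, RR_{i+1})`. Points with
#' `y < x` are accelerations (the successor beat is faster), `y > x`
#' decelerations, `y = x` lie on the identity line.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @return List of class `poincare_points`: `x`, `y`, and counts
#'   `n_accel`, `n_decel`, `n_online`.
#' @export
poincare_points <- function(rri) {
  v <- rri_values(rri)
  if (length(v) < 2L) stop("poincare_points(): need at least 2 intervals")
  x <- v[-length(v)]
  y <- v[-1]
  structure(list(x = x, y = y,
                 n_accel = sum(y < x), n_decel = sum(y > x),
                 n_online = sum(y == x)),
            class = "poincare_points")
}

#' Poincare ellipse metrics SD1, SD2 and their ratio
#'
#' SD1 is the dispersion perpendicular to the identity line (instantaneous,
#' vagally driven variability), SD2 the dispersion along it (longer-term
#' variability): `SD1 = sqrt(Var(dRR) / 2)` and
#' `SD2 = sqrt(2 Var(RR) - Var(dRR) / 2)` with sample variances, reported in
#' ms. If the SD2 radicand is negative it is clipped to zero and flagged.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @return List: `sd1`, `sd2` (ms), `ratio` (`sd1/sd2`, `NA` flagged when
#'   `sd2` is 0), and logical `clipped`.
#' @export
ellipse_metrics <- function(rri) {
  x <- rri_values(rri)
  if (length(x) < 3L) stop("ellipse_metrics(): need at least 3 intervals")
  vd <- stats::var(diff(x))
  vx <- stats::var(x)
  sd1 <- sqrt(vd / 2) * 1000
  rad <- 2 * vx - vd / 2
  clipped <- rad < 0
  sd2 <- sqrt(max(rad, 0)) * 1000
  list(sd1 = sd1, sd2 = sd2,
       ratio = if (sd2 > 0) sd1 / sd2 else NA_real_,
       clipped = clipped)
}

#' Heart-rate asymmetry indices PI, GI, SI, AI (as |X - 50|)
#'
#' Four functionals contrast the contribution of accelerations (points below
#' the identity line) against all off-line points, each expressed as the
#' absolute deviation of the acceleration percentage from the 50% symmetry
#' baseline:
#' \itemize{
#'   \item Porta's index (PI): share of point \emph{counts}.
#'   \item Guzik's index (GI): share of \emph{vertical distances}
#'     `|y - x|` to the identity line.
#'   \item Slope index (SI): share of absolute \emph{phase angles}
#'     `|45 deg - atan2(y, x)|`.
#'   \item Area index (AI): share of \emph{sector areas}
#'     `r^2 theta / 2` with `r = sqrt(x^2 + y^2)` and `theta` the phase
#'     angle in radians.
#' }
#' Points exactly on the identity line are excluded from numerator and
#' denominator of all four indices. A value of 0 indicates perfect
#' acceleration/deceleration symmetry; each index lies in \[0, 50\].
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param gi_mode `"linear"` (default) sums the vertical distances
#'   themselves; `"squared"` uses the classic squared-perpendicular-distance
#'   Guzik variant.
#' @return List with `pi`, `gi`, `si`, `ai` (each in \[0, 50\], `NA` with
#'   `degenerate = TRUE` when every point lies on the identity line).
#' @export
asymmetry_metrics <- function(rri, gi_mode = c("linear", "squared")) {
  gi_mode <- match.arg(gi_mode)
  pp <- poincare_points(rri)
  off <- pp$y != pp$x
  if (!any(off)) {
    return(list(pi = NA_real_, gi = NA_real_, si = NA_real_, ai = NA_real_,
                degenerate = TRUE))
  }
  x <- pp$x[off]
  y <- pp$y[off]
  accel <- y < x
  dist <- if (gi_mode == "squared") (y - x)^2 / 2 else abs(y - x)
  # phase angle measured from the identity line: |45 deg - atan2(y, x)|,
  # computed in rotated coordinates so mirrored points get bit-identical
  # angles and a mirror-symmetric set yields exactly zero
  theta_rad <- atan2(abs(y - x), x + y)
  theta_deg <- theta_rad * 180 / pi
  area <- (x^2 + y^2) * theta_rad / 2
  # |100 S_A / (S_A + S_D) - 50| written as 50 |S_A - S_D| / (S_A + S_D)
  ratio50 <- function(w) {
    sa <- sum(w[accel]); sd_ <- sum(w[!accel])
    50 * abs(sa - sd_) / (sa + sd_)
  }
  list(pi = ratio50(rep(1, length(x))),
       gi = ratio50(dist),
       si = ratio50(theta_deg),
       ai = ratio50(area),
       degenerate = FALSE)
}

#' Grid-distribution metrics at a single resolution
#'
#' The Poincare plane is covered by a square bounding box over the combined
#' coordinate range, split into `n x n` half-open cells (points on the far
#' edges are assigned to the last cell). GDR is the fraction of occupied
#' cells; GDE is the Shannon entropy (natural log) of the cell-occupancy
#' distribution.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param n Grid resolution (cells per side).
#' @param box `"square"` (default) uses one bounding box over the combined
#'   coordinate range; `"per_axis"` bins each axis over its own range.
#' @return List: `gdr` in (0, 1\], `gde` in nats, logical `degenerate`
#'   (zero coordinate range: `gdr = 1/n^2`, `gde = 0` by convention).
#' @export
grid_metrics_at <- function(rri, n, box = c("square", "per_axis")) {
  stopifnot(n >= 1)
  box <- match.arg(box)
  pp <- if (inherits(rri, "poincare_points")) rri else poincare_points(rri)
  if (box == "square") {
    xlo <- ylo <- min(pp$x, pp$y)
    xhi <- yhi <- max(pp$x, pp$y)
  } else {
    xlo <- min(pp$x); xhi <- max(pp$x)
    ylo <- min(pp$y); yhi <- max(pp$y)
  }
  if (xhi == xlo || yhi == ylo) {
    return(list(gdr = 1 / n^2, gde = 0, degenerate = TRUE))
  }
  ix <- pmin(floor((pp$x - xlo) / ((xhi - xlo) / n)), n - 1)
  iy <- pmin(floor((pp$y - ylo) / ((yhi - ylo) / n)), n - 1)
  cell <- ix * n + iy
  counts <- table(cell)
  p <- as.numeric(counts) / length(pp$x)
  list(gdr = length(counts) / n^2,
       gde = -sum(p * log(p)),
       degenerate = FALSE)
}

#' Multi-resolution grid-distribution metrics GDR and GDE
#'
#' Computes [grid_metrics_at()] for every integer resolution in
#' `[n_min, n_max]` (101 resolutions by default) and averages, so the
#' reported indices are not tied to one arbitrary grid size. Per-resolution
#' traces are retained for sensitivity reporting.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param n_min,n_max Inclusive resolution range.
#' @return List: `gdr`, `gde` (means over the range), `trace` (data frame
#'   `n`, `gdr_n`, `gde_n`), `degenerate`.
#' @export
grid_metrics <- function(rri, n_min = 100, n_max = 200) {
  stopifnot(n_min >= 1, n_max >= n_min)
  pp <- poincare_points(rri)
  ns <- n_min:n_max
  gdr_n <- numeric(length(ns))
  gde_n <- numeric(length(ns))
  degen <- FALSE
  for (i in seq_along(ns)) {
    g <- grid_metrics_at(pp, ns[i])
    gdr_n[i] <- g$gdr
    gde_n[i] <- g$gde
    degen <- degen || g$degenerate
  }
  list(gdr = mean(gdr_n), gde = mean(gde_n),
       trace = data.frame(n = ns, gdr_n = gdr_n, gde_n = gde_n),
       degenerate = degen)
}

#' All 16 HRV metrics for one series
#'
#' Convenience wrapper computing the full panel: SDNN, RMSSD, LF, HF, LF/HF,
#' ApEn, SampEn, SD1, SD2, SD1/SD2, SI, PI, GI, AI, GDR, GDE.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param spectral A [spectral_config()].
#' @param entropy An [entropy_config()].
#' @param grid_range Length-2 integer vector of grid resolutions.
#' @param times Optional cumulative beat times for the spectral metrics
#'   (required when `rri` is a zero-mean detrended residual).
#' @return Named numeric vector of 16 metrics.
#' @export
metric_panel <- function(rri, spectral = spectral_config(),
                         entropy = entropy_config(),
                         grid_range = c(100, 200), times = NULL) {
  x <- rri_values(rri)
  bp <- welch_band_powers(x, spectral, times = times)
  el <- ellipse_metrics(x)
  as <- asymmetry_metrics(x)
  gr <- grid_metrics(x, grid_range[1], grid_range[2])
  c(sdnn = sdnn(x), rmssd = rmssd(x),
    lf = bp$lf, hf = bp$hf, lf_hf = bp$ratio,
    apen = apen(x, entropy), sampen = as.numeric(sampen(x, entropy)),
    sd1 = el$sd1, sd2 = el$sd2, sd1_sd2 = el$ratio,
    si = as$si, pi = as$pi, gi = as$gi, ai = as$ai,
    gdr = gr$gdr, gde = gr$gde)
}

#' Poincare plot with fitted ellipse and quadrant shading
#'
#' Descriptive plot of the successive-interval scatter: identity line,
#' acceleration/deceleration half-planes, and the SD1/SD2 ellipse centred at
#' the mean point.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param main Plot title.
#' @return Invisibly, the [ellipse_metrics()] of the series.
#' @export
plot_poincare <- function(rri, main = "Poincare plot") {
  pp <- poincare_points(rri)
  em <- ellipse_metrics(rri)
  plot(pp$x, pp$y, pch = 16, cex = 0.5, col = "steelblue",
       xlab = "RR(i) [s]", ylab = "RR(i+1) [s]", main = main, asp = 1)
  abline(0, 1, col = "red")
  cx <- mean(pp$x); cy <- mean(pp$y)
  th <- seq(0, 2 * pi, length.out = 200)
  a <- em$sd2 / 1000; b <- em$sd1 / 1000
  ex <- cx + a * cos(th) * cos(pi / 4) - b * sin(th) * sin(pi / 4)
  ey <- cy + a * cos(th) * sin(pi / 4) + b * sin(th) * cos(pi / 4)
  lines(ex, ey, col = "red", lwd = 2)
  invisible(em)
}
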