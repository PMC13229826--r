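#' Extract RR intervals from a set of R peaks
#'
#' @param rpeaks An `rpeak_set` from [detect_rpeaks()], or a numeric vector
#'   of 0-based sample indices with `fs` supplied.
#' @param fs Sampling frequency, required when `rpeaks` is a bare vector.
#' @return An [rri_series()] with provenance `"raw"`; `N - 1` intervals for
#'   `N` peaks, `interval_i = (index_{i+1} - index_i) / fs`.
#' @export
extract_rri <- function(rpeaks, fs = NULL) {
  if (inherits(rpeaks, "rpeak_set")) {
    idx <- rpeaks$indices
    fs <- rpeaks$fs
  } else {
    stopifnot(!is.null(fs))
    idx <- as.numeric(rpeaks)
  }
  if (length(idx) < 2L) stop("extract_rri(): need at least 2 peaks")
  rri_series(diff(idx) / fs, provenance = "raw")
}

#' Quality-control filter for RR-interval series
#'
#' Two rules, applied in order:
#' \enumerate{
#'   \item Bounds: intervals outside `[low, high]` seconds are
#'     unconditionally discarded as physiologically implausible at rest.
#'   \item Relative change, evaluated on the bounds-cleaned (spliced)
#'     series: whenever `|RR[i+1] - RR[i]| / RR[i]` exceeds `rel_change`
#'     (the earlier interval is the denominator), both members of the pair
#'     are flagged as an abnormal cluster and removed. Because an aberrant
#'     interval violates the rule against both of its neighbours, the
#'     chained violations flag the neighbours of an ectopic pair as well.
#' }
#' Removed intervals are spliced out, not interpolated. If more than half of
#' the input is removed the recording is deemed unusable and an error is
#' raised.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param low,high Absolute bounds in seconds.
#' @param rel_change Maximum tolerated adjacent relative change.
#' @param max_removed_frac Fraction of removals above which the series is
#'   rejected.
#' @return An [rri_series()] with provenance `"cleaned"` and attribute
#'   `qc_report`: a data frame of removed intervals (original index, value,
#'   rule).
#' @export
qc_filter <- function(rri, low = 0.3, high = 2.0, rel_change = 0.20,
                      max_removed_frac = 0.5) {
  x <- rri_values(rri)
  n <- length(x)
  if (n == 0L) stop("qc_filter(): empty series")
  orig_idx <- seq_len(n)
  bounds_bad <- x < low | x > high
  report <- data.frame(index = orig_idx[bounds_bad],
                       value = x[bounds_bad],
                       rule = rep("bounds", sum(bounds_bad)),
                       stringsAsFactors = FALSE)
  x1 <- x[!bounds_bad]
  idx1 <- orig_idx[!bounds_bad]
  m <- length(x1)
  cluster_bad <- logical(m)
  if (m >= 2L) {
    relchg <- abs(diff(x1)) / x1[-m]
    viol <- which(relchg > rel_change)
    cluster_bad[viol] <- TRUE
    cluster_bad[viol + 1L] <- TRUE
  }
  if (any(cluster_bad)) {
    report <- rbind(report,
                    data.frame(index = idx1[cluster_bad],
                               value = x1[cluster_bad],
                               rule = "rel_change",
                               stringsAsFactors = FALSE))
  }
  removed <- sum(bounds_bad) + sum(cluster_bad)
  if (removed > max_removed_frac * n) {
    stop(sprintf(
      "qc_filter(): %d of %d intervals (%.0f%%) removed; recording unusable",
      removed, n, 100 * removed / n))
  }
  keep_idx <- idx1[!cluster_bad]
  flags <- data.frame(valid = TRUE, bounds_reject = FALSE,
                      cluster_flag = FALSE)[rep(1L, length(keep_idx)), ]
  rownames(flags) <- NULL
  out <- rri_series(x[keep_idx], provenance = "cleaned", flags = flags,
                    id = if (inherits(rri, "rri_series")) rri$id else NULL)
  report <- report[order(report$index), ]
  rownames(report) <- NULL
  attr(out, "qc_report") <- report
  out
}

#' Smoothness-priors detrending of an RR-interval series
#'
#' Fits a smooth trend `tau = (I + lambda^2 t(D2) D2)^{-1} z`, where `D2` is
#' the second-difference operator, and returns the stationary residual
#' `z - tau`. Straight lines lie in the null space of the penalty and are
#' reproduced exactly, so the residual of a linear series is zero. The
#' regularizer enters as `lambda^2` with the conventional default
#' `lambda = 500`; larger values give a smoother (stiffer) trend.
#'
#' @param rri An [rri_series()] (typically cleaned) or numeric vector.
#' @param lambda Smoothing strength (dimensionless, default 500).
#' @param order Difference order of the penalty (default 2).
#' @return A list of class `detrended_rri`: `residual`, `trend` (seconds,
#'   `residual + trend` reconstructs the input), `lambda`, `diff_order`,
#'   `mean_rr`.
#' @export
smoothness_priors_detrend <- function(rri, lambda = 500, order = 2) {
  z <- rri_values(rri)
  n <- length(z)
  if (n < order + 2L) stop("smoothness_priors_detrend(): series too short")
  D <- diff_operator(n, order)
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D)
  trend <- as.numeric(Matrix::solve(A, z))
  structure(list(residual = z - trend, trend = trend,
                 lambda = lambda, diff_order = order, mean_rr = mean(z)),
            class = "detrended_rri")
}

# Sparse k-th order difference operator, (n-k) x n.
diff_operator <- function(n, k) {
  coef <- choose(k, 0:k) * (-1)^(k:0)
  Matrix::bandSparse(n - k, n, k = 0:k,
                     diagonals = lapply(coef, rep, n - k))
}

#' Series used for metric computation under the detrended condition
#'
#' By default the zero-mean residual itself is analysed. For the
#' position-dependent Poincare indices (SI and AI, whose phase angles and
#' radii are measured from the origin) this convention makes the detrended
#' values roughly an order of magnitude larger than the raw ones and
#' sensitive to successive-difference skewness, which is the behaviour
#' short-term HRV studies report; with `restore_mean = TRUE` the mean RR is
#' added back first, which leaves SI and AI on the same scale as the raw
#' condition. All other panel metrics are invariant to this choice.
#'
#' @param d A `detrended_rri`.
#' @param restore_mean Add `mean_rr` back to the residual (default FALSE).
#' @return Numeric vector of intervals (seconds).
#' @export
detrended_values <- function(d, restore_mean = FALSE) {
  stopifnot(inherits(d, "detrended_rri"))
  if (restore_mean) d$residual + d$mean_rr else d$residual
}

#' @export
print.detrended_rri <- function(x, ...) {
  cat(sprintf("<detrended_rri> n=%d, lambda=%g, order=%d, mean RR %.3f s\n",
              length(x$residual), x$lambda, x$diff_order, x$mean_rr))
  invisible(x)
}

#' Read / write RR-interval text files
#'
#' One interval per line; seconds by default, milliseconds with `ms = TRUE`.
#'
#' @param path File path.
#' @param ms Interpret (or write) values as milliseconds.
#' @return `read_rri()`: an [rri_series()] in seconds.
#' @export
read_rri <- function(path, ms = FALSE) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (ms) v <- v / 1000
  rri_series(v, provenance = "raw")
}

#' @rdname read_rri
#' @param rri Series to write.
#' @export
write_rri <- function(rri, path, ms = FALSE) {
  v <- rri_values(rri)
  if (ms) v <- v * 1000
  writeLines(format_rri(v), path)
  invisible(path)
}
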