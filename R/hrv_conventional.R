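#' Time-domain HRV metrics
#'
#' `sdnn()` is the sample standard deviation of the whole series and
#' `rmssd()` the root mean square of successive differences, both in
#' milliseconds.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @return Value in ms.
#' @export
sdnn <- function(rri) {
  x <- rri_values(rri)
  if (length(x) < 2L) stop("sdnn(): need at least 2 intervals")
  stats::sd(x) * 1000
}

#' @rdname sdnn
#' @export
rmssd <- function(rri) {
  x <- rri_values(rri)
  if (length(x) < 2L) stop("rmssd(): need at least 2 intervals")
  sqrt(mean(diff(x)^2)) * 1000
}

#' Spectral-analysis configuration
#'
#' @param resample_rate Uniform resampling rate of the tachogram, Hz.
#' @param segment_length Welch segment length, samples.
#' @param overlap Fractional overlap between segments.
#' @param nfft FFT length (zero-padded).
#' @param lf_band,hf_band Frequency bands in Hz; LF is treated as half-open
#'   `[lo, hi)` and HF as closed `[lo, hi]` so the shared 0.15 Hz edge is
#'   assigned to HF.
#' @param interp Resampling interpolant: `"spline"` (default) or `"linear"`.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(resample_rate = 4, segment_length = 256,
                            overlap = 0.5, nfft = 1024,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                            interp = c("spline", "linear")) {
  interp <- match.arg(interp)
  stopifnot(lf_band[2] <= hf_band[1], hf_band[2] < resample_rate / 2,
            overlap >= 0, overlap < 1, nfft >= segment_length)
  structure(as.list(environment()), class = "spectral_config")
}

# Welch power spectral density with a Hamming window and per-segment mean
# removal. Returns one-sided PSD (units^2 / Hz) on the nfft frequency grid.
welch_psd <- function(x, fs, seg_len, overlap, nfft) {
  n <- length(x)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- signal::hamming(seg_len)
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - seg_len)))
    p <- Mod(X[seq_len(nfft %/% 2 + 1L)])^2 / (fs * u)
    acc <- acc + p
  }
  psd <- acc / length(starts)
  psd[2:(nfft %/% 2)] <- 2 * psd[2:(nfft %/% 2)]  # one-sided (not DC/Nyquist)
  list(freq = (0:(nfft %/% 2)) * fs / nfft, psd = psd)
}

#' Welch band powers of the RR tachogram
#'
#' The tachogram is interpolated onto a uniform grid (default 4 Hz) over the
#' cumulative beat times, Welch's periodogram is computed with a Hamming
#' window, 50% overlap and a zero-padded FFT, and band powers are obtained
#' by trapezoidal integration of the one-sided PSD. Powers are reported in
#' ms^2.
#'
#' @param rri An [rri_series()] or numeric vector (seconds).
#' @param cfg A [spectral_config()].
#' @param times Optional cumulative beat times (seconds) at which the values
#'   are observed. Defaults to `cumsum` of the values themselves, which is
#'   only meaningful for a positive interval series; a detrended (zero-mean)
#'   residual must be supplied together with the beat times of the series it
#'   was derived from.
#' @return List with `lf` (ms^2), `hf` (ms^2), `ratio` (LF/HF), and the
#'   `freq`/`psd` grid (PSD in ms^2/Hz) for plotting.
#' @export
welch_band_powers <- function(rri, cfg = spectral_config(), times = NULL) {
  x <- rri_values(rri)
  if (is.null(times)) {
    if (any(x <= 0)) {
      stop("welch_band_powers(): series has non-positive values; ",
           "supply the beat times via `times`")
    }
    times <- cumsum(x)
  }
  stopifnot(length(times) == length(x), !is.unsorted(times))
  tt <- times
  dur <- tt[length(tt)] - tt[1]
  min_dur <- 2 * cfg$segment_length / cfg$resample_rate
  if (dur < min_dur) {
    stop(sprintf("welch_band_powers(): series spans %.1f s; at least %.0f s required",
                 dur, min_dur))
  }
  grid <- seq(tt[1], tt[length(tt)], by = 1 / cfg$resample_rate)
  y <- if (cfg$interp == "spline") {
    stats::spline(tt, x, xout = grid)$y
  } else {
    stats::approx(tt, x, xout = grid)$y
  }
  sp <- welch_psd(y, cfg$resample_rate, cfg$segment_length, cfg$overlap, cfg$nfft)
  psd_ms2 <- sp$psd * 1e6
  band_power <- function(lo, hi, closed_hi) {
    sel <- if (closed_hi) sp$freq >= lo & sp$freq <= hi
           else sp$freq >= lo & sp$freq < hi
    f <- sp$freq[sel]
    p <- psd_ms2[sel]
    if (length(f) < 2L) return(0)
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  }
  lf <- band_power(cfg$lf_band[1], cfg$lf_band[2], closed_hi = FALSE)
  hf <- band_power(cfg$hf_band[1], cfg$hf_band[2], closed_hi = TRUE)
  list(lf = lf, hf = hf, ratio = if (hf > 0) lf / hf else NA_real_,
       freq = sp$freq, psd = psd_ms2)
}

#' Entropy configuration
#'
#' @param m Embedding dimension (template length).
#' @param r_frac Tolerance as a fraction of the series standard deviation.
#' @return A list of class `entropy_config`.
#' @export
entropy_config <- function(m = 2L, r_frac = 0.2) {
  stopifnot(m >= 1, r_frac > 0)
  structure(list(m = as.integer(m), r_frac = r_frac), class = "entropy_config")
}

# Chebyshev distance matrix between all m-length templates of x.
# Returns (N - m + 1)^2 matrix.
template_dist <- function(x, m) {
  n <- length(x) - m + 1L
  d <- abs(outer(x[1:n], x[1:n], "-"))
  if (m > 1L) {
    for (k in 1:(m - 1L)) {
      dk <- abs(outer(x[(1 + k):(n + k)], x[(1 + k):(n + k)], "-"))
      d <- pmax(d, dk)
    }
  }
  d
}

#' Approximate entropy
#'
#' `ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r)` with self-matches included,
#' Chebyshev distance, and tolerance `r = r_frac * sd(x)`. Lower values
#' indicate a more regular, more predictable series.
#'
#' @param x Numeric series (an RRI series or any stationary signal).
#' @param cfg An [entropy_config()].
#' @return Dimensionless entropy value.
#' @export
apen <- function(x, cfg = entropy_config()) {
  x <- rri_values(x)
  m <- cfg$m
  if (length(x) < 10 * m) stop("apen(): series too short (need >= 10 * m)")
  r <- cfg$r_frac * stats::sd(x)
  phi <- function(mm) {
    d <- template_dist(x, mm)
    nn <- nrow(d)
    ci <- rowSums(d <= r) / nn
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts template pairs (i != j, both
#' drawn from the first `N - m` positions) matching at length `m` and `A`
#' those matching at length `m + 1`; self-matches are excluded. Tolerance
#' `r = r_frac * sd(x)` (so the value is invariant under affine transforms
#' of the series). If no matches exist the value is `+Inf` with attribute
#' `degenerate = TRUE` rather than an error.
#'
#' @inheritParams apen
#' @return Dimensionless entropy value.
#' @export
sampen <- function(x, cfg = entropy_config()) {
  x <- rri_values(x)
  m <- cfg$m
  n <- length(x)
  if (n < 10 * m) stop("sampen(): series too short (need >= 10 * m)")
  r <- cfg$r_frac * stats::sd(x)
  np <- n - m  # both A and B use the first n - m templates
  dm <- template_dist(x, m)[1:np, 1:np]
  dm1 <- template_dist(x, m + 1L)  # (n - m) x (n - m)
  B <- (sum(dm <= r) - np) / 2
  A <- (sum(dm1 <= r) - np) / 2
  if (A == 0 || B == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  -log(A / B)
}
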