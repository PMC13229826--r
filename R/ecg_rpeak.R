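#' Detector configuration for Pan-Tompkins R-peak detection
#'
#' @param band Passband of the QRS-enhancement Butterworth filter, Hz.
#' @param order Butterworth order (applied forward-backward, zero phase).
#' @param integration_window Moving-average window, seconds.
#' @param min_peak_interval Minimum spacing between candidate peaks, seconds.
#' @param twave_window Window after an accepted peak within which a candidate
#'   is screened by the T-wave slope rule, seconds.
#' @param refractory Absolute refractory period, seconds.
#' @param refine_window Half-width of the apex-refinement search, seconds.
#' @param spk_weight,npk_weight Update weights of the running signal-peak and
#'   noise-peak level estimates.
#' @param thresh_frac Threshold position between the noise and signal levels.
#' @param searchback_factor Multiples of the running RR estimate after which
#'   a search-back at half threshold is triggered.
#' @param twave_slope_frac A candidate inside `twave_window` is rejected when
#'   its maximal absolute slope is below this fraction of the previous
#'   accepted peak's.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(band = c(5, 15), order = 3,
                            integration_window = 0.150,
                            min_peak_interval = 0.2,
                            twave_window = 0.36,
                            refractory = 0.2,
                            refine_window = 0.150,
                            spk_weight = 1 / 8, npk_weight = 1 / 8,
                            thresh_frac = 0.25,
                            searchback_factor = 1.66,
                            twave_slope_frac = 0.5) {
  stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2],
            integration_window > 0, min_peak_interval > 0,
            twave_window > 0, refractory > 0, refine_window > 0)
  structure(as.list(environment()), class = "detector_config")
}

#' Zero-phase Butterworth bandpass filter
#'
#' @param ecg An [ecg_record()] or numeric vector (with `fs` supplied).
#' @param band Length-2 passband in Hz; must lie below the Nyquist frequency.
#' @param fs Sampling frequency, required when `ecg` is a bare vector.
#' @param order Filter order.
#' @return Filtered numeric vector, same length as the input.
#' @export
bandpass <- function(ecg, band = c(5, 15), fs = NULL, order = 3) {
  if (inherits(ecg, "ecg_record")) {
    fs <- ecg$fs
    x <- ecg$samples
  } else {
    stopifnot(!is.null(fs))
    x <- as.numeric(ecg)
  }
  nyq <- fs / 2
  if (band[2] >= nyq) {
    stop(sprintf("bandpass(): upper band edge %g Hz is not below the Nyquist frequency %g Hz (fs = %g Hz)",
                 band[2], nyq, fs))
  }
  bf <- signal::butter(order, band / nyq, type = "pass")
  # remove the mean first: DC is outside the passband and subtracting it
  # avoids start-up transients of the forward-backward filter
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Pan-Tompkins feature transform: derivative, squaring, integration
#'
#' Applies the classic five-point differencing kernel
#' `y[n] = (2x[n] + x[n-1] - x[n-3] - 2x[n-4]) / 8` (scaled by `fs` and
#' centre-aligned), squares the result, and smooths with a moving-average
#' window of `round(win * fs)` samples.
#'
#' @param x Filtered signal (numeric).
#' @param fs Sampling frequency, Hz.
#' @param win Integration window in seconds (default 0.150).
#' @return List with `energy` (integrated non-negative signal) and `deriv`
#'   (the centre-aligned derivative), both the same length as `x`.
#' @export
feature_transform <- function(x, fs, win = 0.150) {
  n <- length(x)
  wlen <- max(1L, round(win * fs))
  stopifnot(n > wlen)
  # five-point derivative, centre-aligned (kernel spans n-4..n, centre n-2)
  d <- numeric(n)
  idx <- 3:(n - 2L)
  d[idx] <- (2 * x[idx + 2L] + x[idx + 1L] - x[idx - 1L] - 2 * x[idx - 2L]) / 8 * fs
  sq <- d^2
  energy <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  energy[is.na(energy)] <- 0
  list(energy = energy, deriv = d)
}

# Local maxima of a signal with a minimum-separation constraint,
# resolved greedily in descending amplitude order.
local_peaks <- function(x, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > 0]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      lo <- max(1L, i - min_dist)
      hi <- min(n, i + min_dist)
      blocked[lo:hi] <- TRUE
    }
  }
  sort(which(keep))
}

#' Detect R peaks with an adaptive-threshold Pan-Tompkins chain
#'
#' Bandpass filtering, five-point differencing, squaring and moving-window
#' integration produce an energy signal whose candidate peaks are screened by
#' adaptive signal/noise thresholds, a minimum-interval constraint, a
#' refractory period, a T-wave slope rule, and a search-back pass at half
#' threshold when no peak is found within `searchback_factor` times the
#' running RR estimate. Each accepted candidate is relocated to the local
#' maximum of the absolute bandpassed signal within `refine_window`.
#'
#' Thresholds adapt to the signal level, so detection is invariant to global
#' amplitude scaling of the input.
#'
#' @param ecg An [ecg_record()].
#' @param cfg A [detector_config()].
#' @return A list of class `rpeak_set` with `indices` (0-based sample
#'   indices, strictly increasing, spacing >= the refractory period) and
#'   `fs`. Empty, with a warning, if no peaks pass.
#' @export
detect_rpeaks <- function(ecg, cfg = detector_config()) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  n <- length(ecg$samples)
  if (n < 2 * fs) stop("detect_rpeaks(): need at least 2 s of signal")
  bp <- bandpass(ecg$samples, band = cfg$band, fs = fs, order = cfg$order)
  ft <- feature_transform(bp, fs, cfg$integration_window)
  energy <- ft$energy
  deriv <- ft$deriv

  min_dist <- round(cfg$min_peak_interval * fs)
  cand <- local_peaks(energy, min_dist)
  if (!length(cand)) {
    warning("detect_rpeaks(): no candidate peaks found")
    return(structure(list(indices = integer(0), fs = fs), class = "rpeak_set"))
  }

  # initialise running levels from the first 2 s (fall back to global stats)
  init <- energy[seq_len(min(n, round(2 * fs)))]
  spki <- max(init)
  npki <- mean(init)
  if (spki <= npki) {
    spki <- max(energy)
    npki <- stats::median(energy)
  }
  thr <- function() npki + cfg$thresh_frac * (spki - npki)

  refr <- round(cfg$refractory * fs)
  twin <- round(cfg$twave_window * fs)
  accepted <- integer(0)
  acc_slope <- numeric(0)
  rr_est <- NA_real_
  last_acc <- -Inf
  slope_at <- function(i) {
    lo <- max(1L, i - round(0.075 * fs))
    hi <- min(n, i + round(0.075 * fs))
    max(abs(deriv[lo:hi]))
  }
  for (ci in cand) {
    pk <- energy[ci]
    # search-back: no accepted peak for too long -> revisit skipped
    # candidates at half threshold
    if (is.finite(last_acc) && !is.na(rr_est) &&
        (ci - last_acc) > cfg$searchback_factor * rr_est) {
      missed <- cand[cand > last_acc + refr & cand < ci]
      missed <- missed[energy[missed] > thr() / 2]
      if (length(missed)) {
        mi <- missed[which.max(energy[missed])]
        accepted <- c(accepted, mi)
        acc_slope <- c(acc_slope, slope_at(mi))
        if (length(accepted) >= 2L) {
          d <- diff(utils::tail(accepted, 8L))
          rr_est <- mean(d)
        }
        spki <- 0.25 * energy[mi] + 0.75 * spki
        last_acc <- mi
      }
    }
    if (pk > thr() && (ci - last_acc) >= refr) {
      sl <- slope_at(ci)
      # T-wave rule: low-slope candidate shortly after an accepted peak
      if (is.finite(last_acc) && (ci - last_acc) <= twin &&
          sl < cfg$twave_slope_frac * utils::tail(acc_slope, 1L)) {
        npki <- cfg$npk_weight * pk + (1 - cfg$npk_weight) * npki
        next
      }
      accepted <- c(accepted, ci)
      acc_slope <- c(acc_slope, sl)
      spki <- cfg$spk_weight * pk + (1 - cfg$spk_weight) * spki
      if (length(accepted) >= 2L) {
        d <- diff(utils::tail(accepted, 8L))
        rr_est <- mean(d)
      }
      last_acc <- ci
    } else {
      npki <- cfg$npk_weight * pk + (1 - cfg$npk_weight) * npki
    }
  }
  if (!length(accepted)) {
    warning("detect_rpeaks(): no peaks passed the adaptive threshold")
    return(structure(list(indices = integer(0), fs = fs), class = "rpeak_set"))
  }

  # refine each accepted candidate to the apex of the bandpassed signal
  rw <- round(cfg$refine_window * fs)
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - rw)
    hi <- min(n, i + rw)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period on refined apices, keeping the larger apex
  if (length(refined) > 1L) {
    keep <- rep(TRUE, length(refined))
    j <- 1L
    for (i in 2:length(refined)) {
      if (refined[i] - refined[j] < refr) {
        if (abs(bp[refined[i]]) > abs(bp[refined[j]])) {
          keep[j] <- FALSE
          j <- i
        } else keep[i] <- FALSE
      } else j <- i
    }
    refined <- refined[keep]
  }
  structure(list(indices = as.integer(refined - 1L), fs = fs),
            class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}
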