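#' Construct an ECG record
#'
#' A uniformly sampled single-lead voltage trace together with its sampling
#' frequency. This is the input container for R-peak detection.
#'
#' @param samples Numeric vector of voltages (mV).
#' @param fs Sampling frequency in Hz (> 0).
#' @param id Optional subject identifier.
#' @return An object of class `ecg_record` with elements `samples`, `fs`, `id`.
#' @export
ecg_record <- function(samples, fs, id = NULL) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), length(fs) == 1L, fs > 0)
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs), id = id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$id)) "" else paste0(" id=", x$id)))
  invisible(x)
}

#' Construct an RR-interval series
#'
#' Ordered beat-to-beat intervals in seconds with per-interval validity flags
#' and provenance (`"raw"` straight from peak detection or a generator,
#' `"cleaned"` after quality control).
#'
#' @param intervals Numeric vector of intervals in seconds.
#' @param provenance `"raw"` or `"cleaned"`.
#' @param flags Optional data frame with one row per interval and logical
#'   columns `valid`, `bounds_reject`, `cluster_flag`.
#' @param id Optional subject identifier.
#' @return An object of class `rri_series`.
#' @export
rri_series <- function(intervals, provenance = c("raw", "cleaned"),
                       flags = NULL, id = NULL) {
  provenance <- match.arg(provenance)
  intervals <- as.numeric(intervals)
  if (is.null(flags)) {
    flags <- data.frame(valid = rep(TRUE, length(intervals)),
                        bounds_reject = FALSE, cluster_flag = FALSE)
  }
  stopifnot(nrow(flags) == length(intervals))
  structure(list(intervals = intervals, provenance = provenance,
                 flags = flags, id = id),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series:%s> %d intervals, mean RR %.3f s%s\n",
              x$provenance, length(x$intervals), mean(x$intervals),
              if (all(x$flags$valid)) "" else
                sprintf(" (%d flagged invalid)", sum(!x$flags$valid))))
  invisible(x)
}

# Accept either an rri_series or a bare numeric vector of intervals (seconds).
rri_values <- function(rri) {
  if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
}
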