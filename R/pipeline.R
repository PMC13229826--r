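#' Pipeline configuration
#'
#' Bundles every stage's settings so a whole run is reproducible from one
#' object; the configuration (and its hash) is serialized alongside every
#' output.
#'
#' @param detector A [detector_config()].
#' @param qc_low,qc_high,qc_rel_change Quality-control thresholds (seconds /
#'   fraction).
#' @param lambda,diff_order Smoothness-priors detrending settings.
#' @param spectral A [spectral_config()].
#' @param entropy An [entropy_config()].
#' @param grid_range Length-2 grid resolution range.
#' @param restore_mean Compute detrended-condition metrics on
#'   mean-restored residuals instead of the zero-mean residuals
#'   (default FALSE; affects only SI and AI).
#' @param alpha,folds,seed Statistics settings.
#' @param mode Input mode, `"rri"` or `"ecg"`.
#' @param fs Sampling frequency for ECG mode.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detector = detector_config(),
                            qc_low = 0.3, qc_high = 2.0, qc_rel_change = 0.20,
                            lambda = 500, diff_order = 2,
                            spectral = spectral_config(),
                            entropy = entropy_config(),
                            grid_range = c(100, 200),
                            restore_mean = FALSE,
                            alpha = 0.05, folds = 10, seed = 1L,
                            mode = c("rri", "ecg"), fs = 400) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Hash of a pipeline configuration
#' @param config A [pipeline_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [pipeline_config()]; nested
#' `detector`, `spectral` and `entropy` blocks override the corresponding
#' sub-configurations field by field.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (blk in c("detector", "spectral", "entropy")) {
    if (!is.null(y[[blk]])) {
      for (nm in names(y[[blk]])) cfg[[blk]][[nm]] <- y[[blk]][[nm]]
      y[[blk]] <- NULL
    }
  }
  for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  cfg
}

#' Run the full pipeline for one subject
#'
#' ECG mode: peak detection, RRI extraction, QC, then the 16-metric panel on
#' the cleaned (raw-condition) series and on the smoothness-priors detrended
#' series. RRI mode skips detection and starts at QC. A subject whose
#' recording fails quality control (more than half of the intervals removed)
#' is returned as excluded with a reason code instead of metric values.
#'
#' @param input An [ecg_record()], [rri_series()], numeric vector of
#'   intervals, or a file path (read per `config$mode`).
#' @param config A [pipeline_config()].
#' @param id Optional subject id.
#' @return List of class `subject_result`: `id`, `excluded`, `reason`,
#'   `metrics` (data frame `condition`, `metric`, `value`; 16 rows per
#'   condition), `qc` (removed-interval report), `n_clean`.
#' @export
run_subject <- function(input, config = pipeline_config(), id = NULL) {
  if (is.character(input) && length(input) == 1L) {
    input <- if (config$mode == "ecg") {
      ecg_record(scan(input, what = numeric(), quiet = TRUE), fs = config$fs)
    } else {
      read_rri(input)
    }
  }
  if (inherits(input, "ecg_record")) {
    peaks <- detect_rpeaks(input, config$detector)
    if (length(peaks$indices) < 2L) {
      return(subject_result(id, excluded = TRUE, reason = "no_peaks"))
    }
    raw <- extract_rri(peaks)
  } else {
    raw <- if (inherits(input, "rri_series")) input else rri_series(input)
  }
  clean <- tryCatch(
    qc_filter(raw, config$qc_low, config$qc_high, config$qc_rel_change),
    error = function(e) e)
  if (inherits(clean, "error")) {
    return(subject_result(id, excluded = TRUE, reason = "qc_failed"))
  }
  det <- smoothness_priors_detrend(clean, config$lambda, config$diff_order)
  beat_times <- cumsum(clean$intervals)
  m_raw <- metric_panel(clean, config$spectral, config$entropy,
                        config$grid_range)
  m_det <- metric_panel(detrended_values(det, config$restore_mean),
                        config$spectral, config$entropy, config$grid_range,
                        times = beat_times)
  metrics <- rbind(
    data.frame(condition = "raw", metric = names(m_raw),
               value = unname(m_raw), stringsAsFactors = FALSE),
    data.frame(condition = "detrended", metric = names(m_det),
               value = unname(m_det), stringsAsFactors = FALSE))
  subject_result(id, excluded = FALSE, reason = NA_character_,
                 metrics = metrics, qc = attr(clean, "qc_report"),
                 n_clean = length(clean$intervals))
}

subject_result <- function(id, excluded, reason, metrics = NULL, qc = NULL,
                           n_clean = NA_integer_) {
  structure(list(id = id, excluded = excluded, reason = reason,
                 metrics = metrics, qc = qc, n_clean = n_clean),
            class = "subject_result")
}

#' Run the full pipeline for a cohort manifest
#'
#' Per-subject runs are independent (results do not depend on manifest
#' order). Missing input files are reported and skipped; excluded subjects
#' are listed with their reason code. The assembled wide metric table is
#' joined with the manifest covariates and passed to [build_report()].
#'
#' @param manifest Path to a cohort CSV with columns
#'   `subject_id,path,group,age,menopause,pr,ki67` (paths relative to the
#'   manifest), or an equivalent data frame (then `dir` must locate files).
#' @param config A [pipeline_config()].
#' @param out Optional output directory; when given, metric and statistics
#'   tables plus a provenance JSON (config hash, seed) are written there.
#' @return List of class `cohort_result`: `table` (wide per-subject metric
#'   columns named `<metric>_<condition>` joined with covariates), `report`
#'   (from [build_report()]), `excluded`, `missing`, `config_hash`.
#' @export
run_cohort <- function(manifest, config = pipeline_config(), out = NULL) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    man$path <- file.path(dir, man$path)
  } else {
    man <- manifest
  }
  need <- c("subject_id", "path", "group")
  stopifnot(all(need %in% names(man)))
  missing <- man$subject_id[!file.exists(man$path)]
  rows <- list()
  excluded <- data.frame(subject_id = character(0), reason = character(0))
  for (i in seq_len(nrow(man))) {
    if (man$subject_id[i] %in% missing) next
    res <- run_subject(man$path[i], config, id = man$subject_id[i])
    if (res$excluded) {
      excluded <- rbind(excluded, data.frame(subject_id = man$subject_id[i],
                                             reason = res$reason))
      next
    }
    w <- stats::setNames(res$metrics$value,
                         paste0(res$metrics$metric, "_", res$metrics$condition))
    rows[[man$subject_id[i]]] <- c(list(subject_id = man$subject_id[i]),
                                   as.list(w))
  }
  if (!length(rows)) stop("run_cohort(): no subject completed the pipeline")
  wide <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(wide) <- NULL
  covcols <- intersect(c("subject_id", "group", "age", "menopause", "pr", "ki67"),
                       names(man))
  table <- merge(man[, covcols], wide, by = "subject_id", sort = TRUE)
  metrics <- setdiff(names(wide), "subject_id")
  report <- build_report(table, metrics = metrics,
                         alpha = config$alpha, folds = config$folds,
                         seed = config$seed)
  res <- structure(list(table = table, report = report, excluded = excluded,
                        missing = missing, config_hash = config_hash(config)),
                   class = "cohort_result")
  if (!is.null(out)) write_cohort_result(res, config, out)
  res
}

write_cohort_result <- function(res, config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$table, file.path(out, "metrics.csv"), row.names = FALSE)
  utils::write.csv(res$report$comparison, file.path(out, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(res$report$ancova, file.path(out, "ancova.csv"),
                   row.names = FALSE)
  utils::write.csv(res$report$roc, file.path(out, "roc.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = res$config_hash, seed = config$seed,
         n_subjects = nrow(res$table),
         n_excluded = nrow(res$excluded), n_missing = length(res$missing),
         correction = res$report$meta$correction,
         package = as.character(utils::packageVersion("poincareHRV"))),
    file.path(out, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects, %d excluded, %d missing; config %s\n",
              nrow(x$table), nrow(x$excluded), length(x$missing),
              substr(x$config_hash, 1, 8)))
  invisible(x)
}
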