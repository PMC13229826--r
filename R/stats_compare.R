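#' Normality-gated two-group comparison with Cohen's d
#'
#' Shapiro-Wilk normality is assessed per group at `alpha`; Student's t-test
#' is used only when both groups pass, otherwise the two-sided Mann-Whitney
#' U test. Cohen's d (pooled-SD standardized mean difference) is computed
#' regardless of which test ran, with a 95% CI from the large-sample
#' standard error `sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`. Group
#' summaries follow the normality decision: mean (SD) when normal, median
#' (Q1, Q3) otherwise.
#'
#' @param values Numeric vector of metric values.
#' @param labels Group labels (two levels); the first level encountered with
#'   `group1` naming, see `positive`.
#' @param positive Value of `labels` treated as group 1 (default
#'   `"positive"`, falling back to the first level).
#' @param alpha Normality-gate significance level.
#' @return A one-row data frame: `test`, `p`, `cohens_d`, `d_ci_low`,
#'   `d_ci_high`, `normal`, `summary1`, `summary2`, `n1`, `n2`.
#' @export
compare_groups <- function(values, labels, positive = "positive",
                           alpha = 0.05) {
  labels <- as.character(labels)
  lev <- unique(labels)
  stopifnot(length(lev) == 2L)
  g1 <- if (positive %in% lev) positive else lev[1]
  g2 <- setdiff(lev, g1)
  x1 <- values[labels == g1]
  x2 <- values[labels == g2]
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(n1 >= 3, n2 >= 3)
  sw_ok <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }
  normal <- sw_ok(x1) && sw_ok(x2)
  if (normal) {
    test <- "t"
    p <- stats::t.test(x1, x2, var.equal = TRUE)$p.value
  } else {
    test <- "mann-whitney"
    p <- stats::wilcox.test(x1, x2, exact = FALSE)$p.value
  }
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  if (sp2 > 0) {
    d <- (mean(x1) - mean(x2)) / sqrt(sp2)
    se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
    ci <- d + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    d <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  summ <- function(v) {
    if (normal) sprintf("%.3f ± %.3f", mean(v), stats::sd(v))
    else sprintf("%.3f (%.3f, %.3f)", stats::median(v),
                 stats::quantile(v, 0.25), stats::quantile(v, 0.75))
  }
  data.frame(test = test, p = p, cohens_d = d,
             d_ci_low = ci[1], d_ci_high = ci[2], normal = normal,
             summary1 = summ(x1), summary2 = summ(x2),
             n1 = n1, n2 = n2, stringsAsFactors = FALSE)
}

#' Pearson chi-square test for a 2x2 group-by-factor table
#'
#' @param counts 2x2 integer matrix of counts.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return The p value.
#' @export
chi_square <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi_square(): a table margin is empty")
  }
  stats::chisq.test(counts, correct = correct)$p.value
}

#' Covariate-adjusted group comparison (ANCOVA) with partial eta squared
#'
#' Fits `metric ~ group + covariates` by least squares with the group coded
#' 0/1 and reports the group term's p value given all covariates (for a
#' binary factor this equals the Type-III test) together with partial eta
#' squared, `SS_group / (SS_group + SS_residual)`.
#'
#' @param table Data frame with a `group` column and the named columns.
#' @param metric Name of the outcome column.
#' @param covariates Character vector of covariate column names.
#' @param positive Group level coded 1.
#' @return A one-row data frame: `metric`, `adjusted_p`, `partial_eta_sq`,
#'   `group_coef`, `covariates`.
#' @export
ancova <- function(table, metric,
                   covariates = c("age", "menopause", "pr", "ki67"),
                   positive = "positive") {
  cols <- c(metric, "group", covariates)
  stopifnot(all(cols %in% names(table)))
  dat <- table[stats::complete.cases(table[, cols]), cols]
  if (nrow(dat) < length(covariates) + 3L) {
    stop("ancova(): too few complete cases")
  }
  dat$.group <- as.integer(dat$group == positive)
  form <- stats::reformulate(c(".group", covariates), response = metric)
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("ancova(): collinear terms dropped: ", paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(stats::reformulate(covariates, response = metric),
                       data = dat)
  ss_group <- sum(stats::residuals(reduced)^2) - sum(stats::residuals(fit)^2)
  ss_res <- sum(stats::residuals(fit)^2)
  co <- summary(fit)$coefficients[".group", ]
  data.frame(metric = metric,
             adjusted_p = unname(co["Pr(>|t|)"]),
             partial_eta_sq = ss_group / (ss_group + ss_res),
             group_coef = unname(co["Estimate"]),
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' ROC AUC via the rank (Mann-Whitney) formulation
#'
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the midrank sum of
#' the positive class; ties are handled by midranks. With
#' `orientation = "auto"` the direction giving AUC >= 0.5 is reported and
#' recorded.
#'
#' @param values Numeric marker values.
#' @param labels Binary labels.
#' @param positive Label treated as the positive class.
#' @param orientation `"auto"` or `"fixed"` (higher value predicts positive).
#' @return A one-row data frame: `auc`, `orientation` (`">"` when higher
#'   values indicate the positive class, `"<"` otherwise), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(values, labels, positive = "positive",
                    orientation = c("auto", "fixed")) {
  orientation <- match.arg(orientation)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("roc_auc(): both classes must be present")
  r <- rank(values)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  dir <- ">"
  if (orientation == "auto" && auc < 0.5) {
    auc <- 1 - auc
    dir <- "<"
  }
  data.frame(auc = auc, orientation = dir, n_pos = n1, n_neg = n0,
             stringsAsFactors = FALSE)
}

# Stratified k-fold assignment, reproducible under the current RNG state.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < k) stop("stratified_folds(): class smaller than k")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated ROC analysis of a single marker
#'
#' Stratified k-fold cross-validation: in each fold a univariable logistic
#' score is fit on the training subjects and applied to the held-out
#' subjects; pooled validation scores give the cross-validated AUC, and
#' sensitivity/specificity are reported at the Youden-optimal threshold of
#' the pooled scores.
#'
#' @param values Numeric marker values.
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment (recorded).
#' @param positive Label treated as the positive class.
#' @return A one-row data frame: `cv_auc`, `cv_sensitivity`,
#'   `cv_specificity`, `folds`, `seed`.
#' @export
cv_roc <- function(values, labels, k = 10, seed = 1L, positive = "positive") {
  pos <- labels == positive
  stopifnot(sum(pos) >= k, sum(!pos) >= k)
  restore <- set_local_seed(seed)
  on.exit(restore())
  fold <- stratified_folds(ifelse(pos, "p", "n"), k)
  score <- numeric(length(values))
  for (f in seq_len(k)) {
    tr <- fold != f
    dtr <- data.frame(y = as.integer(pos[tr]), x = values[tr])
    fit <- suppressWarnings(
      stats::glm(y ~ x, data = dtr, family = stats::binomial()))
    score[!tr] <- stats::predict(fit, newdata = data.frame(x = values[!tr]))
  }
  auc <- roc_auc(score, ifelse(pos, "positive", "negative"),
                 orientation = "fixed")$auc
  # Youden-optimal operating point on the pooled validation scores
  thr <- sort(unique(score))
  cuts <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  best <- c(sens = NA_real_, spec = NA_real_, j = -Inf)
  for (ct in cuts) {
    pred <- score > ct
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    if (sens + spec - 1 > best["j"]) {
      best <- c(sens = sens, spec = spec, j = sens + spec - 1)
    }
  }
  data.frame(cv_auc = auc, cv_sensitivity = unname(best["sens"]),
             cv_specificity = unname(best["spec"]),
             folds = k, seed = as.integer(seed), stringsAsFactors = FALSE)
}

#' Full statistical report for a cohort metric table
#'
#' Runs [compare_groups()] for every metric/condition column, [ancova()] for
#' those with unadjusted p < `alpha`, and apparent plus cross-validated ROC
#' for the headline metric and any comparators. No multiple-testing
#' correction is applied; uncorrected p values are reported (recorded in the
#' output metadata).
#'
#' @param table Data frame with `group`, covariates, and metric columns.
#' @param metrics Character vector of metric column names (default: all
#'   numeric columns other than the covariates).
#' @param covariates Covariate column names for the ANCOVA.
#' @param roc_metrics Metric columns to run ROC analysis on (default: the
#'   ANCOVA-significant metrics, capped at 3, else the smallest-p metric).
#' @param alpha Significance level.
#' @param folds,seed Cross-validation settings.
#' @return List of data frames `comparison`, `ancova`, `roc`, plus
#'   `meta` (alpha, correction policy, seed).
#' @export
build_report <- function(table, metrics = NULL,
                         covariates = c("age", "menopause", "pr", "ki67"),
                         roc_metrics = NULL, alpha = 0.05,
                         folds = 10, seed = 1L) {
  stopifnot("group" %in% names(table))
  if (is.null(metrics)) {
    num <- vapply(table, is.numeric, logical(1))
    metrics <- setdiff(names(table)[num], c(covariates, "age"))
  }
  comp <- do.call(rbind, lapply(metrics, function(m) {
    cbind(metric = m, compare_groups(table[[m]], table$group))
  }))
  sig <- comp$metric[comp$p < alpha]
  anc <- if (length(sig)) {
    do.call(rbind, lapply(sig, function(m) ancova(table, m, covariates)))
  } else {
    data.frame(metric = character(0), adjusted_p = numeric(0),
               partial_eta_sq = numeric(0), group_coef = numeric(0),
               covariates = character(0))
  }
  if (is.null(roc_metrics)) {
    roc_metrics <- if (length(sig)) utils::head(sig, 3) else
      comp$metric[which.min(comp$p)]
  }
  k_eff <- min(folds, table(table$group))
  roc <- do.call(rbind, lapply(roc_metrics, function(m) {
    cbind(metric = m,
          roc_auc(table[[m]], table$group),
          cv_roc(table[[m]], table$group, k = k_eff, seed = seed))
  }))
  list(comparison = comp, ancova = anc, roc = roc,
       meta = list(alpha = alpha, correction = "none (uncorrected p values)",
                   folds = folds, seed = as.integer(seed)))
}
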