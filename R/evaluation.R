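#' Subject-grouped k-fold assignment
#'
#' Shuffles the unique subjects by seed and deals them round-robin into `k`
#' folds, so fold sizes differ by at most one and every measurement of a
#' subject shares its fold. This is the grouping that keeps repeated
#' measurements of one person from straddling train and test.
#'
#' @param subject_ids Character vector (one entry per measurement, or the
#'   unique subjects).
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return Named integer vector: fold (1..k) per unique subject.
#' @export
grouped_kfold <- function(subject_ids, k = 10, seed = 1) {
  subjects <- unique(subject_ids)
  if (k > length(subjects)) stopf("k (%d) exceeds the number of subjects (%d)", k, length(subjects))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(subjects)
  folds <- rep(seq_len(k), length.out = length(shuffled))
  stats::setNames(folds, shuffled)
}

#' Out-of-fold scores and decisions via grouped cross-validation
#'
#' For each fold, trains the full classifier head on the other folds only:
#' median imputation fitted on training rows, AdaBoost training, operating
#' point at maximal training balanced accuracy, NA-zone calibration on
#' training scores. The held-out fold is then imputed with the training
#' medians, scored and classified, so every measurement is scored exactly
#' once by a model that never saw its subject.
#'
#' @param features Feature data.frame from [assemble_feature_matrix()]
#'   (`measurement_id`, `subject_id`, `label`, feature columns).
#' @param config A [pipeline_config()].
#' @return A data.frame (`measurement_id`, `subject_id`, `label`, `fold`,
#'   `score`, `decision`).
#' @export
cross_validated_scores <- function(features, config = pipeline_config()) {
  meta <- c("measurement_id", "subject_id", "label")
  fcols <- setdiff(colnames(features), meta)
  X <- as.matrix(features[, fcols, drop = FALSE])
  y <- features$label
  folds <- grouped_kfold(features$subject_id, k = config$k, seed = config$seed)
  fold_of <- folds[features$subject_id]
  out <- features[, meta, drop = FALSE]
  out$fold <- as.integer(fold_of)
  out$score <- NA_real_
  out$decision <- NA_character_
  for (f in sort(unique(fold_of))) {
    tr <- fold_of != f; te <- fold_of == f
    if (length(unique(y[tr])) < 2) {
      warning(sprintf("fold %d skipped: single-class training split", f))
      next
    }
    imp <- fit_imputation(X[tr, , drop = FALSE])
    Xtr <- apply_imputation(X[tr, , drop = FALSE], imp)
    fit <- train_adaboost(Xtr, y[tr], n_rounds = config$n_rounds)
    model <- fit$model
    str_scores <- score_measurements(model, Xtr)
    model$operating_threshold <- select_operating_point(str_scores, y[tr])
    model$na_zone <- calibrate_na_zone(str_scores, y[tr],
                                       model$operating_threshold,
                                       max_na_frac = config$max_na_frac)
    Xte <- apply_imputation(X[te, , drop = FALSE], imp)
    res <- classify_measurements(model, Xte, features$measurement_id[te])
    out$score[te] <- res$score
    out$decision[te] <- res$decision
  }
  out
}

#' ROC curve and AUC
#'
#' Operating points at every distinct score threshold; AUC by the trapezoid
#' rule, which equals the Mann-Whitney U probability statistic (ties counted
#' half).
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case indicators.
#' @return A list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- to_pm1(labels) == 1
  if (!any(y) || all(y)) stopf("both classes are required for a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = mean(pred[!y]), tpr = mean(pred[y]))
  }, numeric(2)))
  pts <- rbind(c(fpr = 0, tpr = 0), pts)
  # the lowest threshold predicts everything positive, so the curve ends at (1, 1)
  auc <- sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) + utils::tail(pts[, "tpr"], -1)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), fpr = pts[, "fpr"], tpr = pts[, "tpr"]),
       auc = auc)
}

#' Confusion counts from decisions
#'
#' @param decisions Character vector in `{"case", "control", "inconclusive"}`.
#' @param labels Case indicators.
#' @param na_policy `"exclude"` removes inconclusives from the counts
#'   (tracked in `n_inconclusive`); `"count_as_error"` books an inconclusive
#'   case as a false negative and an inconclusive control as a false
#'   positive.
#' @return A list of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `n_inconclusive`.
#' @export
confusion_counts <- function(decisions, labels,
                             na_policy = c("exclude", "count_as_error")) {
  na_policy <- match.arg(na_policy)
  y <- to_pm1(labels) == 1
  inc <- decisions == "inconclusive"
  tp <- sum(decisions == "case" & y)
  fp <- sum(decisions == "case" & !y)
  tn <- sum(decisions == "control" & !y)
  fn <- sum(decisions == "control" & y)
  if (na_policy == "count_as_error") {
    fn <- fn + sum(inc & y)
    fp <- fp + sum(inc & !y)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n_inconclusive = sum(inc)),
            class = "confusion_counts")
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Sensitivity, specificity, balanced accuracy, predictive values both at the
#' sample prevalence (raw counts) and re-derived by Bayes' identity at an
#' external prevalence, and the likelihood ratios
#' `PLR = Se / (1 - Sp)`, `NLR = (1 - Se) / Sp`. A specificity of 1 yields an
#' infinite PLR marker.
#'
#' @param cc A [confusion_counts()].
#' @param prevalence External prevalence for `ppv_at_p` / `npv_at_p`.
#' @return Named list of point estimates.
#' @export
diagnostic_metrics <- function(cc, prevalence = 0.32) {
  if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0)
    stopf("both classes must be present in the confusion counts")
  se <- cc$tp / (cc$tp + cc$fn)
  sp <- cc$tn / (cc$tn + cc$fp)
  p <- prevalence
  list(
    sensitivity = se,
    specificity = sp,
    balanced_accuracy = (se + sp) / 2,
    ppv_sample = if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_,
    npv_sample = if (cc$tn + cc$fn > 0) cc$tn / (cc$tn + cc$fn) else NA_real_,
    ppv_at_p = se * p / (se * p + (1 - sp) * (1 - p)),
    npv_at_p = sp * (1 - p) / (sp * (1 - p) + (1 - se) * p),
    plr = if (sp < 1) se / (1 - sp) else Inf,
    nlr = if (sp > 0) (1 - se) / sp else NA_real_
  )
}

#' Subject-clustered bootstrap confidence interval
#'
#' Resamples subjects with replacement (all measurements of a drawn subject
#' travel together), recomputes the statistic on each resample, and returns
#' the percentile interval. Resamples on which the statistic is undefined are
#' dropped; more than 20% undefined marks the interval failed.
#'
#' @param stat_fn Function `data -> number`, where `data` is the row-subset
#'   of `data` for a resample.
#' @param data A data.frame with a `subject_id` column.
#' @param n_boot Number of resamples.
#' @param seed RNG seed.
#' @param level Confidence level.
#' @return A list: `lo`, `hi`, `failed`, `n_failed`.
#' @export
bootstrap_ci <- function(stat_fn, data, n_boot = 1000, seed = 1, level = 0.95) {
  subjects <- unique(data$subject_id)
  rows_of <- split(seq_len(nrow(data)), data$subject_id)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stats_v <- vapply(seq_len(n_boot), function(b) {
    draw <- sample(subjects, length(subjects), replace = TRUE)
    idx <- unlist(rows_of[draw], use.names = FALSE)
    val <- tryCatch(stat_fn(data[idx, , drop = FALSE]), error = function(e) NA_real_)
    if (is.null(val) || !is.finite(val)) NA_real_ else val
  }, numeric(1))
  n_failed <- sum(is.na(stats_v))
  failed <- n_failed > 0.2 * n_boot
  qs <- if (failed) c(NA_real_, NA_real_) else
    stats::quantile(stats_v, c((1 - level) / 2, 1 - (1 - level) / 2),
                    na.rm = TRUE, names = FALSE, type = 7)
  list(lo = qs[1], hi = qs[2], failed = failed, n_failed = n_failed)
}

#' Full diagnostic report with bootstrap confidence intervals
#'
#' Computes the complete metric panel (sensitivity, specificity, balanced
#' accuracy, AUC, predictive values at sample and external prevalence,
#' likelihood ratios) from out-of-fold scores, each with a subject-clustered
#' bootstrap percentile interval, plus the observed inconclusive fraction.
#'
#' @param cv_scores Output of [cross_validated_scores()].
#' @param config A [pipeline_config()] (prevalence, bootstrap and NA-policy
#'   settings).
#' @return A list of class `diagnostic_report`: per metric a
#'   `c(estimate, lo, hi)` triple, plus `na_fraction`, `counts`, `config`
#'   echoes.
#' @export
diagnostic_report <- function(cv_scores, config = pipeline_config()) {
  scored <- cv_scores[!is.na(cv_scores$score), , drop = FALSE]
  metric_fns <- list(
    sensitivity = function(d) pointwise_metrics(d, config)$sensitivity,
    specificity = function(d) pointwise_metrics(d, config)$specificity,
    balanced_accuracy = function(d) pointwise_metrics(d, config)$balanced_accuracy,
    auc = function(d) roc_curve(d$score, d$label)$auc,
    ppv_sample = function(d) pointwise_metrics(d, config)$ppv_sample,
    npv_sample = function(d) pointwise_metrics(d, config)$npv_sample,
    ppv_at_p = function(d) pointwise_metrics(d, config)$ppv_at_p,
    npv_at_p = function(d) pointwise_metrics(d, config)$npv_at_p,
    plr = function(d) pointwise_metrics(d, config)$plr,
    nlr = function(d) pointwise_metrics(d, config)$nlr
  )
  est <- lapply(metric_fns, function(f) f(scored))
  cis <- lapply(metric_fns, function(f)
    bootstrap_ci(f, scored, n_boot = config$n_boot, seed = config$seed))
  out <- stats::setNames(lapply(names(metric_fns), function(nm)
    c(estimate = est[[nm]], lo = cis[[nm]]$lo, hi = cis[[nm]]$hi)),
    names(metric_fns))
  out$na_fraction <- mean(scored$decision == "inconclusive")
  out$counts <- confusion_counts(scored$decision, scored$label, config$na_policy)
  out$prevalence <- config$prevalence
  out$na_policy <- config$na_policy
  structure(out, class = "diagnostic_report")
}

# metrics of one (possibly resampled) decision table under the config's policy
pointwise_metrics <- function(d, config) {
  diagnostic_metrics(confusion_counts(d$decision, d$label, config$na_policy),
                     prevalence = config$prevalence)
}

#' Effect of measurement duration on diagnostic performance
#'
#' Crops every measurement to its first `d` seconds for each duration in the
#' sweep, re-runs feature extraction and grouped cross-validation, and
#' reports the metrics at the per-duration maximal-balanced-accuracy
#' operating point.
#'
#' @param measurements List of `vibration_measurement`, all at least as long
#'   as `max(durations)`.
#' @param cohort Cohort table.
#' @param config A [pipeline_config()].
#' @param durations Durations to evaluate, s.
#' @return A data.frame with one row per duration: `duration`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `auc`, `na_fraction`.
#' @export
duration_sweep <- function(measurements, cohort, config = pipeline_config(),
                           durations = seq(30, 120, by = 5)) {
  max_d <- max(durations)
  for (m in measurements)
    if (length(m$samples) / m$fs < max_d - 1e-9)
      stopf("measurement %s shorter than %g s", m$measurement_id, max_d)
  rows <- lapply(durations, function(d) {
    cropped <- lapply(measurements, crop_measurement, duration_s = d)
    cfg_d <- config
    cfg_d$buffer_s <- min(config$buffer_s, d)
    fm <- assemble_feature_matrix(cropped, cohort, cfg_d)
    cv <- cross_validated_scores(fm$features, cfg_d)
    scored <- cv[!is.na(cv$score), , drop = FALSE]
    m <- pointwise_metrics(scored, cfg_d)
    data.frame(duration = d, sensitivity = m$sensitivity,
               specificity = m$specificity,
               balanced_accuracy = m$balanced_accuracy,
               auc = roc_curve(scored$score, scored$label)$auc,
               na_fraction = mean(scored$decision == "inconclusive"))
  })
  do.call(rbind, rows)
}
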