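#' ROC curve and area under it
#'
#' Builds the full ROC staircase over all score thresholds (prediction is
#' `score > threshold`, strict) and integrates it by the trapezoidal rule.
#' The trapezoid AUC equals the Mann-Whitney pair statistic
#' `U / (n1 * n0)` with ties counted 1/2.
#'
#' @param scores Numeric scores (higher = more event-like).
#' @param labels Logical (or 0/1) event labels; both classes must be present.
#' @return List of class `ih_roc`: `roc` (tibble `threshold`, `fpr`, `tpr`)
#'   and scalar `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    abort("`scores` and `labels` must be equal-length and complete")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores[labels] > t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] > t) / n0, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(roc = tibble(threshold = thr, fpr = fpr, tpr = tpr), auc = auc),
            class = "ih_roc")
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 = TPR - FPR over the ROC
#' points; ties are broken toward the lowest cutoff.
#'
#' @param roc ROC points tibble (`threshold`, `fpr`, `tpr`) from
#'   [roc_auc()], or an `ih_roc` object.
#' @return List with `cutoff` and `j`.
#' @export
youden_cutoff <- function(roc) {
  if (inherits(roc, "ih_roc")) roc <- roc$roc
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  pick <- best[which.min(roc$threshold[best])]
  list(cutoff = roc$threshold[pick], j = j[pick])
}

#' Classification metrics at a fixed cutoff
#'
#' Confusion counts with prediction `score > cutoff` (strict), and the
#' derived metrics: accuracy, sensitivity (= recall), specificity, precision
#' and F1 (`2 * precision * recall / (precision + recall)`, computed in the
#' robust form `2TP / (2TP + FP + FN)`).
#'
#' @param scores,labels As in [roc_auc()].
#' @param cutoff Decision cutoff.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`, `recall`, `precision`, `f1`.
#' @export
threshold_metrics <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  pred <- scores > cutoff
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels)
  fn <- sum(!pred & labels)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  )
}

#' Fivefold cross-validation of the full modeling pipeline
#'
#' Stratified k-fold cross-validation in which the *entire* pipeline —
#' median imputation, RFE-CV feature selection, hyperparameter grid search,
#' forest fit and Youden cutoff — is re-run inside each training split, so no
#' validation row influences any fitted component. Metrics are computed on
#' each held-out fold at the fold model's cutoff.
#'
#' @param table Feature table for the whole analyzed cohort.
#' @param outcome Outcome column name.
#' @param config An [rf_config()].
#' @param k Number of folds (default 5); each class must have at least `k`
#'   members.
#' @param seed Fold-assignment seed (defaults to `config$seed`).
#' @param features Candidate feature columns handed to [rfe_cv()]; defaults
#'   to the intersection of [feature_names()] with the table's columns.
#' @return Object of class `ih_cv`: `folds` (per-fold metrics tibble incl.
#'   AUC and selected feature count) and `summary` (mean and SD per metric).
#' @export
kfold_cv <- function(table, outcome, config = rf_config(), k = 5,
                     seed = config$seed, features = NULL) {
  y <- as.logical(table[[outcome]])
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  if (min(base::table(y)) < k) abort(sprintf("each class needs at least k = %d members", k))
  folds <- make_folds(y, k, seed)
  per_fold <- map(seq_len(k), function(i) {
    train <- table[folds != i, , drop = FALSE]
    test <- table[folds == i, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + 1000L * i
    sel <- rfe_cv(train, outcome, features = features, config = cfg)
    model <- fit_rf(train, sel$selected, outcome, cfg)
    p <- predict_proba(model, test)
    m <- threshold_metrics(p, test[[outcome]], model$cutoff)
    m$auc <- if (length(unique(as.logical(test[[outcome]]))) == 2) {
      roc_auc(p, test[[outcome]])$auc
    } else NA_real_
    m$fold <- i
    m$n_selected <- length(sel$selected)
    m
  })
  folds_tbl <- list_rbind(per_fold)
  metrics <- c("accuracy", "sensitivity", "specificity", "recall", "f1", "auc")
  summary_tbl <- tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_tbl[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(m) sd(folds_tbl[[m]], na.rm = TRUE), numeric(1))
  )
  structure(list(k = k, folds = folds_tbl, summary = summary_tbl, outcome = outcome),
            class = "ih_cv")
}

#' Group comparison of cohort variables
#'
#' Compares each variable between event-positive and event-negative patients
#' the way clinical baseline tables are built: binary variables by chi-square
#' test; continuous variables by Student's t test when Shapiro-Wilk finds no
#' evidence against normality (p > 0.05) in *both* groups — summarized as
#' mean (SD) — and by the Mann-Whitney U test otherwise — summarized as
#' median [IQR]. Zero-variance variables are skipped with a note.
#'
#' @param table Feature table.
#' @param outcome Outcome column name defining the two groups.
#' @param variables Variables to compare; defaults to [feature_names()].
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per variable: group sizes and means, formatted
#'   group summaries, the test used, its statistic, `p_value`, and
#'   `significant`.
#' @export
group_compare <- function(table, outcome, variables = feature_names(), alpha = 0.05) {
  g <- as.logical(table[[outcome]])
  if (sum(g) == 0 || sum(!g) == 0) abort("both groups must be nonempty")
  rows <- map(variables, function(v) {
    x <- table[[v]]
    ok <- !is.na(x)
    xp <- x[ok & g]
    xn <- x[ok & !g]
    base <- tibble(variable = v, n_pos = length(xp), n_neg = length(xn),
                   mean_pos = mean(xp), mean_neg = mean(xn))
    if (var(c(xp, xn)) == 0) {
      return(dplyr::bind_cols(base, tibble(
        summary_pos = NA_character_, summary_neg = NA_character_,
        test = "skipped (zero variance)", statistic = NA_real_, p_value = NA_real_
      )))
    }
    if (length(unique(x[ok])) <= 2) {
      tab <- base::table(factor(g[ok], c(FALSE, TRUE)), factor(x[ok]))
      ct <- suppressWarnings(chisq.test(tab))
      smry <- function(v) sprintf("%d (%.1f%%)", sum(v == max(x[ok])),
                                  100 * mean(v == max(x[ok])))
      return(dplyr::bind_cols(base, tibble(
        summary_pos = smry(xp), summary_neg = smry(xn),
        test = "chi-square", statistic = unname(ct$statistic), p_value = ct$p.value
      )))
    }
    normal <- function(v) {
      if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) return(FALSE)
      shapiro.test(v)$p.value > alpha
    }
    if (normal(xp) && normal(xn)) {
      tt <- t.test(xp, xn)
      smry <- function(v) sprintf("%.2f (%.2f)", mean(v), sd(v))
      dplyr::bind_cols(base, tibble(
        summary_pos = smry(xp), summary_neg = smry(xn),
        test = "t", statistic = unname(tt$statistic), p_value = tt$p.value
      ))
    } else {
      wt <- suppressWarnings(wilcox.test(xp, xn))
      smry <- function(v) sprintf("%.2f [%.2f, %.2f]", median(v),
                                  quantile(v, 0.25), quantile(v, 0.75))
      dplyr::bind_cols(base, tibble(
        summary_pos = smry(xp), summary_neg = smry(xn),
        test = "Mann-Whitney U", statistic = unname(wt$statistic), p_value = wt$p.value
      ))
    }
  })
  out <- list_rbind(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
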