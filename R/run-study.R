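#' Full study configuration
#'
#' Bundles every stage's parameters: the cohort simulator, preprocessing
#' (epoch length, smoothing span, feature window), the outcome definition
#' (threshold and minimum durations), inclusion rules, the train/test split
#' and the random-forest workflow. Unknown arguments are rejected.
#'
#' @param sim A [sim_config()].
#' @param rf An [rf_config()].
#' @param complexity A [complexity_params()].
#' @param feature_window_h Feature window, hours (default 6).
#' @param epoch_s Epoch length, seconds (default 12).
#' @param smooth_span Moving-average span in epochs (default 4).
#' @param index_window_epochs PRx/RAP correlation window (default 30).
#' @param ih_threshold IH threshold, mmHg (default 22).
#' @param ih_min,sih_min Minimum episode durations in minutes that IH / SIH
#'   events must exceed (defaults 5 and 60).
#' @param min_record_h Minimum recording length, hours (default 18).
#' @param train_fraction Training fraction of the 70/30 split (default 0.7).
#' @param seed Master seed threaded into every stochastic stage.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(sim = sim_config(), rf = rf_config(),
                         complexity = complexity_params(),
                         feature_window_h = 6, epoch_s = 12, smooth_span = 4,
                         index_window_epochs = 30, ih_threshold = 22,
                         ih_min = 5, sih_min = 60, min_record_h = 18,
                         train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(rf, "rf_config"),
            inherits(complexity, "complexity_params"))
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly in (0, 1)")
  }
  if (!is_number(feature_window_h) || feature_window_h <= 0) abort("bad `feature_window_h`")
  if (!is_number(ih_threshold) || ih_threshold <= 0) abort("bad `ih_threshold`")
  if (!(ih_min < sih_min)) abort("`ih_min` must be smaller than `sih_min`")
  sim$seed <- as.integer(seed)
  rf$seed <- as.integer(seed)
  structure(list(sim = sim, rf = rf, complexity = complexity,
                 feature_window_h = feature_window_h, epoch_s = epoch_s,
                 smooth_span = smooth_span,
                 index_window_epochs = index_window_epochs,
                 ih_threshold = ih_threshold, ih_min = ih_min, sih_min = sih_min,
                 min_record_h = min_record_h, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the end-to-end study replica
#'
#' Simulates (or accepts) a cohort, applies the inclusion filters, extracts
#' the 11-feature table with IH/SIH labels, compares groups, and for each
#' prediction task (IH, SIH) runs the complete modeling workflow: 70/30
#' stratified split, RFE-CV feature selection on the training partition, VIF
#' screening of the selected set, grid-searched random-forest fit with Youden
#' cutoff, test-set metrics and ROC/AUC, feature importances, and fivefold
#' cross-validation of the full pipeline on the whole included cohort.
#'
#' @param config A [study_config()].
#' @param cohort Optional pre-built cohort tibble (as from [sim_cohort()]);
#'   when `NULL` (default) a cohort is simulated from `config$sim`.
#' @param tasks Prediction tasks to run (default `c("ih", "sih")`).
#' @return Object of class `ih_study`: the config, a manifest (seed, config
#'   hash, package version), cohort and exclusion tables, the feature table,
#'   per-outcome group comparisons, and one result list per task (`split`,
#'   `rfe`, `vif`, `model`, `test_scores`, `test_metrics`, `test_roc`,
#'   `importance`, `cv`).
#' @export
run_study <- function(config = study_config(), cohort = NULL, tasks = c("ih", "sih")) {
  stopifnot(inherits(config, "study_config"))
  tasks <- match.arg(tasks, c("ih", "sih"), several.ok = TRUE)
  if (is.null(cohort)) cohort <- sim_cohort(config$sim)
  cohort <- apply_inclusion_filters(cohort, min_record_h = config$min_record_h,
                                    threshold_mmHg = config$ih_threshold,
                                    feature_window_h = config$feature_window_h)
  features <- build_feature_table(
    cohort, feature_window_h = config$feature_window_h, epoch_s = config$epoch_s,
    smooth_span = config$smooth_span,
    index_window_epochs = config$index_window_epochs, params = config$complexity,
    ih_threshold = config$ih_threshold, ih_min = config$ih_min,
    sih_min = config$sih_min, min_record_h = config$min_record_h
  )
  groups <- lapply(stats::setNames(tasks, tasks), function(task) {
    group_compare(features, task)
  })
  results <- lapply(stats::setNames(tasks, tasks), function(task) {
    split <- stratified_split(features, task, config$train_fraction,
                              seed = config$seed + match(task, c("ih", "sih")))
    rfe <- rfe_cv(split$train, task, config = config$rf)
    vif <- if (length(rfe$selected) >= 2) {
      vif_table(split$train, rfe$selected)
    } else NULL
    model <- fit_rf(split$train, rfe$selected, task, config$rf)
    scores <- predict_proba(model, split$test)
    metrics <- threshold_metrics(scores, split$test[[task]], model$cutoff)
    roc <- roc_auc(scores, split$test[[task]])
    metrics$auc <- roc$auc
    cv <- kfold_cv(features, task, config$rf, k = 5,
                   seed = config$seed + 10L * match(task, c("ih", "sih")))
    list(task = task, split = split, rfe = rfe, vif = vif, model = model,
         test_scores = scores, test_metrics = metrics, test_roc = roc,
         importance = rf_importance(model), cv = cv)
  })
  structure(list(
    config = config,
    manifest = list(seed = config$seed, config_hash = rlang::hash(config),
                    package_version = as.character(utils::packageVersion("ihpredict")),
                    n_simulated = nrow(cohort), n_included = nrow(features)),
    cohort = dplyr::select(cohort, -"recording"),
    exclusions = attr(features, "exclusions"),
    features = features,
    groups = groups,
    results = results
  ), class = "ih_study")
}

#' @export
print.ih_study <- function(x, ...) {
  cat("Intracranial hypertension prediction study\n")
  cat(sprintf("  cohort: %d simulated, %d included (%d excluded)\n",
              x$manifest$n_simulated, x$manifest$n_included,
              x$manifest$n_simulated - x$manifest$n_included))
  cat(sprintf("  events: %d IH (%.1f%%), %d SIH (%.1f%%)\n",
              sum(x$features$ih), 100 * mean(x$features$ih),
              sum(x$features$sih), 100 * mean(x$features$sih)))
  for (task in names(x$results)) {
    r <- x$results[[task]]
    cv_auc <- r$cv$summary[r$cv$summary$metric == "auc", ]
    cat(sprintf("  RF-%s: %d features | test AUC %.2f | 5-fold CV AUC %.2f (%.2f)\n",
                toupper(task), length(r$model$features), r$test_metrics$auc,
                cv_auc$mean, cv_auc$sd))
  }
  invisible(x)
}
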