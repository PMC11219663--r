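#' Tidy and glance methods for fitted objects
#'
#' `tidy()` on an `ih_rf` model returns the per-feature importance table;
#' `glance()` returns a one-row model summary. `tidy()` on an `ih_cv` report
#' returns the per-fold metrics; `glance()` the mean/SD summary in wide form.
#' `glance()` on an `ih_study` returns one row per task with the headline
#' test and cross-validated AUCs.
#'
#' @param x A fitted `ih_rf`, `ih_cv`, `ih_rfe` or `ih_study` object.
#' @param ... Unused.
#' @return A tibble.
#' @name ih-tidiers
NULL

#' @rdname ih-tidiers
#' @export
tidy.ih_rf <- function(x, ...) rf_importance(x)

#' @rdname ih-tidiers
#' @export
glance.ih_rf <- function(x, ...) {
  tibble(outcome = x$outcome, n_features = length(x$features),
         n_trees = x$hyperparams$n_trees, mtry = x$hyperparams$mtry,
         nodesize = x$hyperparams$nodesize, cutoff = x$cutoff,
         youden_j = x$youden_j, oob_auc = x$oob_auc)
}

#' @rdname ih-tidiers
#' @export
tidy.ih_cv <- function(x, ...) x$folds

#' @rdname ih-tidiers
#' @export
glance.ih_cv <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  wide_sd <- stats::setNames(as.list(x$summary$sd), paste0(x$summary$metric, "_sd"))
  dplyr::bind_cols(tibble(outcome = x$outcome, k = x$k),
                   as_tibble(wide), as_tibble(wide_sd))
}

#' @rdname ih-tidiers
#' @export
tidy.ih_rfe <- function(x, ...) x$profile

#' @rdname ih-tidiers
#' @export
glance.ih_study <- function(x, ...) {
  list_rbind(map(names(x$results), function(task) {
    r <- x$results[[task]]
    cv <- r$cv$summary
    tibble(task = task,
           n_included = x$manifest$n_included,
           n_selected = length(r$model$features),
           test_auc = r$test_metrics$auc,
           test_accuracy = r$test_metrics$accuracy,
           test_sensitivity = r$test_metrics$sensitivity,
           test_specificity = r$test_metrics$specificity,
           test_f1 = r$test_metrics$f1,
           cv_auc_mean = cv$mean[cv$metric == "auc"],
           cv_auc_sd = cv$sd[cv$metric == "auc"])
  }))
}

#' @export
print.ih_rf <- function(x, ...) {
  cat(sprintf("Random-forest %s model: %d features, %d trees (mtry %d, nodesize %d)\n",
              toupper(x$outcome), length(x$features), x$hyperparams$n_trees,
              x$hyperparams$mtry, x$hyperparams$nodesize))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  OOB AUC %.3f | Youden cutoff %.3f (J = %.3f)\n",
              x$oob_auc, x$cutoff, x$youden_j))
  invisible(x)
}

#' @export
print.ih_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", x$k, toupper(x$outcome)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.2f (%.2f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
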