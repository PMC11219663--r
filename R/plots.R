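#' Plot an epoch series with the IH threshold
#'
#' ICP, MAP and CPP epoch traces over time with the hypertension threshold
#' marked, the standard way neuromonitoring trends are reviewed.
#'
#' @param es Epoch series tibble.
#' @param threshold_mmHg Threshold line (default 22).
#' @return A ggplot object.
#' @export
plot_epochs <- function(es, threshold_mmHg = 22) {
  long <- tidyr::pivot_longer(es[, c("t_mid_s", "icp", "map", "cpp")],
                              -"t_mid_s", names_to = "channel", values_to = "mmHg")
  long$channel <- toupper(long$channel)
  ggplot(long, aes(x = .data$t_mid_s / 3600, y = .data$mmHg, colour = .data$channel)) +
    geom_line(linewidth = 0.3) +
    geom_hline(yintercept = threshold_mmHg, linetype = "dashed", colour = "red3") +
    labs(x = "Time (h)", y = "Pressure (mmHg)", colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.ih_roc <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    geom_step(colour = "steelblue4", linewidth = 0.7) +
    annotate("text", x = 0.75, y = 0.1, label = sprintf("AUC = %.2f", object$auc)) +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity") +
    theme_minimal()
}

#' @export
autoplot.ih_rfe <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$size, y = .data$mean_cv_auc)) +
    geom_line(colour = "steelblue4") +
    geom_point() +
    geom_vline(xintercept = object$best_size, linetype = "dashed", colour = "red3") +
    scale_x_continuous(breaks = object$profile$size) +
    labs(x = "Number of features", y = "Mean cross-validated AUC") +
    theme_minimal()
}

#' Dot plot of random-forest feature importances
#'
#' Mean Decrease Accuracy and Mean Decrease Gini side by side, features
#' ordered by the permutation measure.
#'
#' @param importance Importance tibble from [rf_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  long <- tidyr::pivot_longer(importance, c("mda", "mdg"),
                              names_to = "measure", values_to = "value")
  long$measure <- ifelse(long$measure == "mda", "Mean Decrease Accuracy",
                         "Mean Decrease Gini")
  long$feature <- factor(long$feature, levels = rev(importance$feature))
  ggplot(long, aes(x = .data$value, y = .data$feature)) +
    geom_point(colour = "steelblue4") +
    facet_wrap(~measure, scales = "free_x") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
autoplot.ih_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              c("accuracy", "sensitivity", "specificity", "f1", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.1, colour = "steelblue4") +
    labs(x = NULL, y = sprintf("%d-fold CV value", object$k)) +
    theme_minimal()
}
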