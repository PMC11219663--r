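#' Random-forest workflow configuration
#'
#' @param n_trees Trees per forest (>= 100; default 500).
#' @param mtry_grid Candidate `mtry` values for the grid search; `NULL`
#'   (default) uses `{1, 2, 3, floor(sqrt(p)) + 1}` truncated to the number of
#'   available features.
#' @param min_node_grid Candidate minimum terminal node sizes (default
#'   `c(1, 5, 10)`).
#' @param inner_cv_folds Folds for the inner cross-validation used by the
#'   feature-elimination profile and the hyperparameter grid search
#'   (default 5).
#' @param seed Seed threaded through every stochastic step.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, mtry_grid = NULL, min_node_grid = c(1, 5, 10),
                      inner_cv_folds = 5, seed = 1L) {
  if (!is_count(n_trees, min = 100)) abort("`n_trees` must be an integer >= 100")
  if (!is.null(mtry_grid) && (length(mtry_grid) == 0 || any(mtry_grid < 1))) {
    abort("`mtry_grid` must be a nonempty vector of positive counts")
  }
  if (length(min_node_grid) == 0 || any(min_node_grid < 1)) {
    abort("`min_node_grid` must be a nonempty vector of positive counts")
  }
  if (!is_count(inner_cv_folds, min = 2)) abort("`inner_cv_folds` must be >= 2")
  structure(list(n_trees = as.integer(n_trees), mtry_grid = mtry_grid,
                 min_node_grid = as.integer(min_node_grid),
                 inner_cv_folds = as.integer(inner_cv_folds),
                 seed = as.integer(seed)),
            class = "rf_config")
}

as_outcome_factor <- function(y) {
  factor(ifelse(as.logical(y), "pos", "neg"), levels = c("neg", "pos"))
}

#' Stratified train/test split
#'
#' Splits the feature table into training and test partitions while
#' preserving the outcome class proportions: within each class,
#' `round(train_fraction * n_class)` rows (at least 1, at most
#' `n_class - 1`) are sampled for training.
#'
#' @param table Feature table.
#' @param outcome Outcome column name (`"ih"` or `"sih"`).
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Seed for the random draw.
#' @return List with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
stratified_split <- function(table, outcome, train_fraction = 0.7, seed = 1L) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1")
  }
  y <- as.logical(table[[outcome]])
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  if (any(tabulate(as.integer(y) + 1L, 2L) < 2)) abort("each class needs at least 2 members")
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(c(FALSE, TRUE), function(cl) {
      rows <- which(y == cl)
      n_tr <- min(max(round(train_fraction * length(rows)), 1), length(rows) - 1)
      sample(rows, n_tr)
    }))
  })
  list(train = table[sort(idx_train), , drop = FALSE],
       test = table[-sort(idx_train), , drop = FALSE])
}

# stratified fold ids; refolds once (seed + 1) if any fold's training part
# loses a class, then errors
make_folds <- function(y, k, seed) {
  assign_folds <- function(s) {
    withr::with_seed(s, {
      f <- integer(length(y))
      for (cl in unique(y)) {
        rows <- sample(which(y == cl))
        f[rows] <- rep_len(seq_len(k), length(rows))
      }
      f
    })
  }
  for (s in c(seed, seed + 1)) {
    f <- assign_folds(s)
    ok <- all(vapply(seq_len(k), function(i) length(unique(y[f != i])) == 2, logical(1)))
    if (ok) return(f)
  }
  abort("degenerate outcome in a cross-validation fold")
}

fit_forest <- function(x, y, n_trees, mtry, nodesize, seed, importance = FALSE) {
  withr::with_seed(seed, {
    randomForest::randomForest(
      x = x, y = as_outcome_factor(y), ntree = n_trees,
      mtry = min(mtry, ncol(x)), nodesize = nodesize, importance = importance
    )
  })
}

impute_medians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- vapply(x, function(v) median(v, na.rm = TRUE), numeric(1))
  }
  for (j in names(x)) {
    miss <- is.na(x[[j]])
    if (any(miss)) x[[j]][miss] <- medians[[j]]
  }
  list(x = x, medians = medians)
}

# mean held-out AUC of a forest over stratified inner folds
inner_cv_auc <- function(x, y, n_trees, mtry, nodesize, k, seed) {
  folds <- make_folds(y, k, seed)
  aucs <- vapply(seq_len(k), function(i) {
    rf <- fit_forest(x[folds != i, , drop = FALSE], y[folds != i],
                     n_trees, mtry, nodesize, seed + i)
    p <- predict(rf, x[folds == i, , drop = FALSE], type = "prob")[, "pos"]
    roc_auc(p, y[folds == i])$auc
  }, numeric(1))
  mean(aucs)
}

#' Recursive feature elimination with cross-validation (RFE-CV)
#'
#' Starting from the full candidate set, repeatedly fits a random forest,
#' removes the feature with the lowest permutation importance (mean decrease
#' accuracy on out-of-bag samples), and records the mean inner-CV AUC at each
#' set size. The returned feature set is the one at the size with the highest
#' mean CV AUC; ties go to the smaller set. Deterministic given
#' `config$seed`.
#'
#' @param train Training feature table (no test rows may enter here).
#' @param outcome Outcome column name.
#' @param features Candidate feature columns; defaults to the intersection of
#'   [feature_names()] with the table's columns.
#' @param config An [rf_config()].
#' @return Object of class `ih_rfe`: `selected` (ordered most- to
#'   least-important), `profile` (tibble `size`, `mean_cv_auc`), `ranking`
#'   (all candidates, elimination order reversed), `best_size`.
#' @export
rfe_cv <- function(train, outcome, features = NULL, config = rf_config()) {
  features <- features %||% intersect(feature_names(), names(train))
  if (length(features) < 1) abort("need at least one candidate feature")
  if (nrow(train) < 10) abort("need at least 10 training rows")
  y <- as.logical(train[[outcome]])
  x <- impute_medians(as.data.frame(train[, features, drop = FALSE]))$x

  current <- features
  eliminated <- character(0)
  sets <- list()
  profile <- tibble(size = integer(0), mean_cv_auc = numeric(0))
  step <- 0L
  while (length(current) >= 1) {
    step <- step + 1L
    auc <- inner_cv_auc(x[, current, drop = FALSE], y, config$n_trees,
                        mtry = max(1, floor(sqrt(length(current)))),
                        nodesize = 1, k = config$inner_cv_folds,
                        seed = config$seed + 97L * step)
    sets[[length(current)]] <- current
    profile <- dplyr::bind_rows(profile,
                                tibble(size = length(current), mean_cv_auc = auc))
    if (length(current) == 1) break
    rf <- fit_forest(x[, current, drop = FALSE], y, config$n_trees,
                     mtry = max(1, floor(sqrt(length(current)))), nodesize = 1,
                     seed = config$seed + 31L * step, importance = TRUE)
    mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    drop_f <- current[which.min(mda)]
    eliminated <- c(eliminated, drop_f)
    current <- setdiff(current, drop_f)
  }
  ranking <- rev(c(eliminated, current)) # survivor first, first-eliminated last
  best_size <- with(profile, min(size[mean_cv_auc == max(mean_cv_auc)]))
  selected <- ranking[ranking %in% sets[[best_size]]]
  structure(list(selected = selected, profile = dplyr::arrange(profile, size),
                 ranking = ranking, best_size = best_size, outcome = outcome),
            class = "ih_rfe")
}

#' Variance inflation factors
#'
#' For each feature, regresses it on the remaining features by least squares
#' and reports `VIF = 1 / (1 - R^2)`. Exact collinearity is reported as
#' `Inf`. VIF above the flag threshold signals multicollinearity.
#'
#' @param table Feature table (rows with missing values in `features` are
#'   dropped).
#' @param features Feature columns to screen (>= 2).
#' @param flag_threshold Flagging threshold (default 5).
#' @return Tibble `feature`, `vif`, `flagged`.
#' @export
vif_table <- function(table, features, flag_threshold = 5) {
  if (length(features) < 2) abort("need at least 2 features for VIF")
  x <- as.data.frame(table[, features, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) <= length(features)) abort("need more rows than features")
  vifs <- vapply(features, function(f) {
    fit <- lm(stats::reformulate(setdiff(features, f), f), data = x)
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(feature = features, vif = unname(vifs), flagged = unname(vifs) > flag_threshold)
}

#' Fit the random-forest classifier
#'
#' Grid search over `mtry` and minimum node size by mean inner-CV AUC (ties
#' resolved toward the first grid entry, i.e. the smaller values), final
#' refit on the full training set, and classification cutoff chosen by
#' Youden's index on the training out-of-bag vote fractions — no test-set
#' information enters the fit, the imputation medians, or the cutoff.
#'
#' @param train Training feature table.
#' @param selected Feature subset to use (e.g. from [rfe_cv()]).
#' @param outcome Outcome column name.
#' @param config An [rf_config()].
#' @return Object of class `ih_rf` with the fitted forest, selected features,
#'   tuned hyperparameters, Youden cutoff, training imputation medians, OOB
#'   vote AUC, and the grid-search table.
#' @export
fit_rf <- function(train, selected, outcome, config = rf_config()) {
  if (length(selected) < 1) abort("`selected` must be nonempty")
  y <- as.logical(train[[outcome]])
  imp <- impute_medians(as.data.frame(train[, selected, drop = FALSE]))
  x <- imp$x
  constant <- vapply(x, function(v) length(unique(v)) == 1, logical(1))
  if (any(constant)) {
    warn(sprintf("dropping all-constant feature(s): %s",
                 paste(names(x)[constant], collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
    selected <- selected[!constant]
    if (length(selected) == 0) abort("all selected features are constant")
  }
  p <- ncol(x)
  mtry_grid <- config$mtry_grid %||% unique(pmin(c(1, 2, 3, floor(sqrt(p)) + 1), p))
  grid <- tidyr::expand_grid(mtry = sort(unique(mtry_grid)),
                             nodesize = sort(unique(config$min_node_grid)))
  grid$mean_cv_auc <- purrr::pmap_dbl(grid, function(mtry, nodesize) {
    inner_cv_auc(x, y, config$n_trees, mtry, nodesize,
                 k = config$inner_cv_folds, seed = config$seed + 7L)
  })
  best <- grid[which.max(grid$mean_cv_auc), ] # which.max: first maximum wins ties
  forest <- fit_forest(x, y, config$n_trees, best$mtry, best$nodesize,
                       seed = config$seed, importance = TRUE)
  oob <- forest$votes[, "pos"]
  roc <- roc_auc(oob, y)
  cut <- youden_cutoff(roc$roc)
  structure(list(
    outcome = outcome,
    features = selected,
    hyperparams = list(n_trees = config$n_trees, mtry = best$mtry,
                       nodesize = best$nodesize),
    forest = forest,
    cutoff = min(max(cut$cutoff, 0), 1),
    youden_j = cut$j,
    train_medians = imp$medians[selected],
    oob_auc = roc$auc,
    grid = grid
  ), class = "ih_rf")
}

#' Predicted event probabilities
#'
#' Fraction of trees voting for the event class. Missing feature values are
#' imputed with the training-set medians stored in the model.
#'
#' @param model An `ih_rf` model from [fit_rf()].
#' @param rows Data frame carrying all selected feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, rows) {
  stopifnot(inherits(model, "ih_rf"))
  missing_cols <- setdiff(model$features, names(rows))
  if (length(missing_cols) > 0) {
    abort(sprintf("rows lack selected feature(s): %s", paste(missing_cols, collapse = ", ")))
  }
  x <- impute_medians(as.data.frame(rows[, model$features, drop = FALSE]),
                      model$train_medians)$x
  as.numeric(predict(model$forest, x, type = "prob")[, "pos"])
}

#' Random-forest feature importances
#'
#' Mean Decrease Accuracy (permutation of out-of-bag samples, unscaled) and
#' Mean Decrease Gini (total impurity decrease) for every feature of a fitted
#' model.
#'
#' @param model An `ih_rf` model fitted with importance recording (the
#'   default in [fit_rf()]).
#' @param order_by `"mda"` (default) or `"mdg"`.
#' @return Tibble `feature`, `mda`, `mdg`, sorted decreasing by the requested
#'   measure.
#' @export
rf_importance <- function(model, order_by = c("mda", "mdg")) {
  stopifnot(inherits(model, "ih_rf"))
  order_by <- match.arg(order_by)
  imp <- randomForest::importance(model$forest, scale = FALSE)
  out <- tibble(feature = rownames(imp),
                mda = unname(imp[, "MeanDecreaseAccuracy"]),
                mdg = unname(imp[, "MeanDecreaseGini"]))
  dplyr::arrange(out, dplyr::desc(.data[[order_by]]))
}
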