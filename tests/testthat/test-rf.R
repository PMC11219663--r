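test_that("stratified split preserves class proportions and is deterministic", {
  set.seed(9)
  tbl <- tibble::tibble(ih = rep(c(TRUE, FALSE), c(60, 40)), x = rnorm(100))
  sp <- stratified_split(tbl, "ih", 0.7, seed = 2)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  expect_equal(sum(duplicated(dplyr::bind_rows(sp$train, sp$test)$x)), 0)
  expect_lte(abs(sum(sp$train$ih) - 42), 1)
  sp2 <- stratified_split(tbl, "ih", 0.7, seed = 2)
  expect_identical(sp$train, sp2$train)

  expect_error(stratified_split(tibble::tibble(ih = rep(TRUE, 10), x = 1:10), "ih"),
               "both outcome classes")
  expect_error(stratified_split(tbl, "ih", 1.0), "strictly between")
})

test_that("VIF matches the two-predictor closed form and flags collinearity", {
  set.seed(19)
  n <- 500
  # orthogonal design: VIF approximately 1
  tbl <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- vif_table(tbl, c("a", "b", "c"))
  expect_true(all(v$vif < 1.05))
  expect_false(any(v$flagged))

  for (rho in c(0.5, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    v2 <- vif_table(tibble::tibble(x = x, y = y), c("x", "y"))
    expect_equal(v2$vif, rep(1 / (1 - rho^2), 2), tolerance = 0.2)
  }

  dup <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  dup$z <- dup$x
  v3 <- vif_table(dup, c("x", "y", "z"))
  expect_true(is.infinite(v3$vif[v3$feature == "x"]))
  expect_true(is.infinite(v3$vif[v3$feature == "z"]))
})

test_that("RFE keeps a single candidate and recovers a planted signal", {
  set.seed(29)
  tbl <- planted_feature_table(150, n_signal = 1, n_noise = 0, effect = 1.5)
  cfg <- rf_config(n_trees = 100, seed = 3)
  r <- rfe_cv(tbl, "ih", features = "sig1", config = cfg)
  expect_equal(r$selected, "sig1")

  tbl2 <- planted_feature_table(200, n_signal = 2, n_noise = 3, effect = 1.2)
  r2 <- rfe_cv(tbl2, "ih", features = setdiff(names(tbl2), "ih"), config = cfg)
  expect_true(all(c("sig1", "sig2") %in% r2$selected))
  expect_equal(nrow(r2$profile), 5)
  expect_equal(r2$best_size, length(r2$selected))
  # deterministic given the config seed
  r3 <- rfe_cv(tbl2, "ih", features = setdiff(names(tbl2), "ih"), config = cfg)
  expect_identical(r2$selected, r3$selected)
})

test_that("fitted forest tunes by inner CV, sets a Youden cutoff, and predicts sanely", {
  set.seed(39)
  tbl <- planted_feature_table(200, n_signal = 2, n_noise = 2, effect = 1.2)
  cfg <- rf_config(n_trees = 100, seed = 7)
  model <- fit_rf(tbl, c("sig1", "sig2", "noise1", "noise2"), "ih", cfg)
  expect_s3_class(model, "ih_rf")
  expect_true(model$cutoff >= 0 && model$cutoff <= 1)
  expect_gt(model$oob_auc, 0.7)
  expect_equal(nrow(model$grid), 9)

  p <- predict_proba(model, tbl)
  expect_true(all(p >= 0 & p <= 1))
  # identical rows get identical probabilities; missing values are imputed
  two <- tbl[c(1, 1), ]
  expect_equal(predict_proba(model, two)[1], predict_proba(model, two)[2])
  holey <- tbl[3, ]
  holey$sig1 <- NA
  expect_true(!is.na(predict_proba(model, holey)))
  expect_error(predict_proba(model, tbl[, "ih"]), "lack selected feature")

  # all-constant features are dropped with a warning
  tbl$flat <- 1
  expect_warning(m2 <- fit_rf(tbl, c("sig1", "flat"), "ih", cfg), "constant")
  expect_equal(m2$features, "sig1")
})

test_that("no test-partition row influences selection, tuning, or cutoff", {
  set.seed(49)
  tbl <- planted_feature_table(120, n_signal = 2, n_noise = 2, effect = 1)
  sp <- stratified_split(tbl, "ih", 0.7, seed = 5)
  cfg <- rf_config(n_trees = 100, seed = 11)
  feats <- setdiff(names(tbl), "ih")
  r1 <- rfe_cv(sp$train, "ih", features = feats, config = cfg)
  m1 <- fit_rf(sp$train, r1$selected, "ih", cfg)
  # scrambling the test partition must change nothing fitted
  scrambled <- sp$test
  for (f in feats) scrambled[[f]] <- rev(scrambled[[f]])
  r2 <- rfe_cv(sp$train, "ih", features = feats, config = cfg)
  m2 <- fit_rf(sp$train, r2$selected, "ih", cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(m1$cutoff, m2$cutoff)
  expect_identical(m1$hyperparams, m2$hyperparams)
  expect_identical(m1$train_medians, m2$train_medians)
})

test_that("permuted labels give chance-level out-of-bag AUC", {
  set.seed(59)
  tbl <- planted_feature_table(150, n_signal = 2, n_noise = 2, effect = 1.2)
  cfg <- rf_config(n_trees = 100, seed = 13)
  aucs <- vapply(1:8, function(i) {
    null_tbl <- tbl
    null_tbl$ih <- sample(null_tbl$ih)
    if (length(unique(null_tbl$ih)) < 2) return(NA_real_)
    fit_rf(null_tbl, c("sig1", "sig2", "noise1", "noise2"), "ih", cfg)$oob_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.12)
})

test_that("forest size perturbations barely move the out-of-bag AUC", {
  set.seed(69)
  tbl <- planted_feature_table(200, n_signal = 2, n_noise = 1, effect = 1.2)
  a <- fit_rf(tbl, c("sig1", "sig2", "noise1"), "ih",
              rf_config(n_trees = 500, seed = 3))$oob_auc
  b <- fit_rf(tbl, c("sig1", "sig2", "noise1"), "ih",
              rf_config(n_trees = 1000, seed = 3))$oob_auc
  expect_lt(abs(a - b), 0.03)
})

test_that("tidy and glance methods expose importances and model summaries", {
  set.seed(79)
  tbl <- planted_feature_table(100, n_signal = 1, n_noise = 1, effect = 1.5)
  model <- fit_rf(tbl, c("sig1", "noise1"), "ih", rf_config(n_trees = 100, seed = 2))
  td <- tidy(model)
  expect_equal(sort(td$feature), c("noise1", "sig1"))
  expect_true(all(td$mdg >= 0))
  expect_equal(td$feature[1], "sig1") # the signal ranks first
  gl <- glance(model)
  expect_equal(gl$n_features, 2)
  expect_true(gl$oob_auc > 0.5)
  imp <- rf_importance(model, order_by = "mdg")
  expect_equal(imp$feature[1], "sig1")
})
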