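test_that("trapezoid AUC equals the pair-counting oracle and handles edge cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(roc_auc(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(10:120, 1)
    scores <- round(runif(n), sample(c(1, 2, 8), 1)) # rounding induces ties
    labels <- rbinom(n, 1, 0.4) == 1
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- runif(300)
  labels <- rbinom(300, 1, plogis(3 * scores - 1.5)) == 1
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("labels independent of scores give chance-level AUC", {
  set.seed(39)
  scores <- runif(2000)
  labels <- rbinom(2000, 1, 0.5) == 1
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.03)
})

test_that("Youden cutoff matches the exhaustive scan, lowest cutoff on ties", {
  set.seed(49)
  for (rep in 1:20) {
    n <- sample(8:60, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5) == 1
    if (length(unique(labels)) < 2) next
    got <- youden_cutoff(roc_auc(scores, labels))
    want <- oracle_youden(scores, labels)
    expect_equal(got$j, want$j, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
  # perfect separation reaches J = 1
  got <- youden_cutoff(roc_auc(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE)))
  expect_equal(got$j, 1)
})

test_that("threshold metrics satisfy their arithmetic identities", {
  # fixed confusion table: TP=10, FN=1, TN=5, FP=4
  scores <- c(rep(0.9, 10), 0.1, rep(0.2, 5), rep(0.8, 4))
  labels <- c(rep(TRUE, 11), rep(FALSE, 9))
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(10, 1, 5, 4))
  expect_equal(m$sensitivity, 10 / 11, tolerance = 1e-12)
  expect_equal(m$specificity, 5 / 9, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.75)
  # J at this cutoff is sensitivity + specificity - 1 = 0.465
  expect_equal(m$sensitivity + m$specificity - 1, 0.46464646, tolerance = 1e-6)

  # all predicted positive
  m2 <- threshold_metrics(scores, labels, -1)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)

  set.seed(59)
  for (rep in 1:100) {
    n <- sample(5:80, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5) == 1
    m <- threshold_metrics(scores, labels, runif(1))
    expect_equal(m$accuracy, (m$tp + m$tn) / n)
    if (!is.na(m$sensitivity)) expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    expect_equal(m$recall, m$sensitivity)
    if (!is.na(m$f1) && !is.na(m$precision) && (m$precision + m$recall) > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("stratified folds partition the cohort with balanced sizes", {
  y <- rep(c(TRUE, FALSE), c(43, 26)) # 69 patients
  folds <- ihpredict:::make_folds(y, 5, seed = 9)
  expect_equal(sort(unique(folds)), 1:5)
  sizes <- as.integer(base::table(folds))
  expect_true(all(sizes %in% 13:15))
  expect_equal(sum(sizes), 69)
  # every fold's training part keeps both classes
  for (i in 1:5) expect_equal(length(unique(y[folds != i])), 2)
})

test_that("cross-validation reruns the full pipeline per fold and summarizes", {
  set.seed(69)
  tbl <- planted_feature_table(60, n_signal = 2, n_noise = 1, effect = 1.5)
  cfg <- rf_config(n_trees = 100, inner_cv_folds = 3, seed = 5)
  cv <- kfold_cv(tbl, "ih", cfg, k = 3, features = setdiff(names(tbl), "ih"))
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(cv$folds$n_selected >= 1))
  s <- cv$summary
  for (met in s$metric) {
    vals <- cv$folds[[met]]
    expect_gte(s$mean[s$metric == met], min(vals, na.rm = TRUE))
    expect_lte(s$mean[s$metric == met], max(vals, na.rm = TRUE))
  }
  expect_error(kfold_cv(tbl[1:6, ], "ih", cfg, k = 5,
                        features = setdiff(names(tbl), "ih")), "at least k")
})

test_that("group comparison routes tests by type and normality", {
  set.seed(79)
  tbl <- tibble::tibble(
    ih = rep(c(TRUE, FALSE), each = 30),
    gauss = rnorm(60) + rep(c(1.4, 0), each = 30),
    skewed = exp(rnorm(60)) * rep(c(2, 1), each = 30),
    sex = rbinom(60, 1, 0.5),
    flat = rep(1, 60)
  )
  gc <- group_compare(tbl, "ih", c("gauss", "skewed", "sex", "flat"))
  expect_equal(gc$test[gc$variable == "gauss"], "t")
  expect_equal(gc$test[gc$variable == "skewed"], "Mann-Whitney U")
  expect_equal(gc$test[gc$variable == "sex"], "chi-square")
  expect_match(gc$test[gc$variable == "flat"], "skipped")
  expect_true(gc$significant[gc$variable == "gauss"])
})

test_that("t test is chosen and powered for shifted normal groups", {
  set.seed(89)
  hits <- 0
  for (rep in 1:30) {
    tbl <- tibble::tibble(ih = rep(c(TRUE, FALSE), each = 30),
                          v = rnorm(60) + rep(c(1.3, 0), each = 30))
    gc <- group_compare(tbl, "ih", "v")
    if (gc$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 27)
})

test_that("null group comparison p-values are approximately uniform", {
  set.seed(99)
  ps <- vapply(1:200, function(i) {
    tbl <- tibble::tibble(ih = rep(c(TRUE, FALSE), each = 25), v = rnorm(50))
    group_compare(tbl, "ih", "v")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
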