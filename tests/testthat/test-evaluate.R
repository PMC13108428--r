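test_that("classification metrics match the 2x2 worked example", {
  truth <- factor(c(rep("pain", 4), rep("no_pain", 6)), levels = c("no_pain", "pain"))
  pred <- factor(c("pain", "pain", "pain", "no_pain", "pain", rep("no_pain", 5)),
                 levels = c("no_pain", "pain"))
  cm <- classification_metrics(truth, pred)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$recall, 0.75)
  expect_equal(cm$specificity, 0.8333, tolerance = 1e-4)
  expect_equal(cm$f1, 0.75)
  expect_equal(cm$mcc, 0.5833, tolerance = 1e-4)
  expect_equal(cm$cohen_kappa, 0.5833, tolerance = 1e-4)
  expect_equal(sum(cm$confusion), 10)
})

test_that("degenerate classification cases flag rather than zero", {
  truth <- factor(c("pain", "no_pain"), levels = c("no_pain", "pain"))
  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  all_neg <- classification_metrics(truth, factor(c("no_pain", "no_pain"),
                                                  levels = c("no_pain", "pain")))
  expect_true(is.na(all_neg$precision))
  expect_error(classification_metrics(factor(character(0)), factor(character(0))),
               "empty")
})

test_that("MCC equals Cohen's kappa on symmetric confusion tables", {
  for (k in c(2, 5, 9)) {
    truth <- factor(rep(c("pain", "no_pain"), each = 10), levels = c("no_pain", "pain"))
    pred <- truth
    pred[c(seq_len(k), 10 + seq_len(k))] <-
      rev(pred[c(seq_len(k), 10 + seq_len(k))])
    cm <- classification_metrics(truth, pred)
    expect_equal(cm$mcc, cm$cohen_kappa, tolerance = 1e-12)
  }
})

test_that("AUC follows rank statistics and its bootstrap CI covers the null", {
  expect_equal(auc_with_ci(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.1, 0.4),
                           n_boot = 50)$auc, 1.0)
  expect_equal(auc_with_ci(rep(c(TRUE, FALSE), 10), rep(0.5, 20),
                           n_boot = 50)$auc, 0.5)
  expect_equal(auc_with_ci(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.1, 0.4),
                           curve = "pr", n_boot = 50)$auc, 1.0)
  expect_error(auc_with_ci(rep(TRUE, 5), rnorm(5)), "both classes")
  covered <- vapply(1:50, function(s) {
    set.seed(2000 + s)
    y <- rep(c(TRUE, FALSE), each = 100)
    ci <- auc_with_ci(y, rnorm(200), n_boot = 300, seed = s)
    ci$lo <= 0.5 && ci$hi >= 0.5
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("regression metrics match the worked triple and definitions", {
  rm_ <- regression_metrics(c(52, 58, 71), c(50, 60, 70))
  expect_equal(rm_$mae, 1.667, tolerance = 1e-3)
  expect_equal(rm_$rmse, 1.732, tolerance = 1e-3)
  expect_equal(rm_$pct_within_5, 100)
  x <- c(10, 20, 30)
  expect_equal(regression_metrics(x, x)$mae, 0)
  expect_equal(regression_metrics(x, x)$r2, 1)
  expect_equal(regression_metrics(x, rep(mean(x), 3))$r2, 0)
  withz <- regression_metrics(c(0, 10, 20), c(1, 11, 19))
  expect_true(is.na(withz$mape_pct))
  expect_false(is.na(withz$mae))
  # RMSE >= MAE for arbitrary inputs
  for (s in 1:10) {
    set.seed(s)
    a <- runif(20, 1, 100); p <- a + rnorm(20, 0, 10)
    r <- regression_metrics(a, p)
    expect_gte(r$rmse, r$mae)
    expect_gte(r$pct_within_10, r$pct_within_5)
    expect_gte(r$pct_within_15, r$pct_within_10)
  }
})

test_that("severity strata use the clinical CoVAS boundaries", {
  sm <- stratified_metrics(c(0, 0, 15, 30, 31, 75, 90),
                           c("no_pain", "pain", "pain", "pain", "pain", "pain", "no_pain"))
  expect_equal(sm$n[sm$stratum == "mild"], 2)      # 15 and 30
  expect_equal(sm$n[sm$stratum == "moderate"], 1)  # 31
  expect_equal(sm$specificity[sm$stratum == "no_pain"], 0.5)
  empty <- stratified_metrics(c(5, 10), c("pain", "pain"))
  expect_true(is.na(empty$recall[empty$stratum == "severe"]))
  expect_equal(empty$n[empty$stratum == "severe"], 0)
})

test_that("severe pain is recalled at least as well as mild pain", {
  tab <- strong_feature_table()
  wins <- vapply(1:20, function(s) {
    m <- suppressWarnings(fit_cascade(tab, cascade_config(seed = 3000 + s,
                                                          n_trees = 60)))
    pred <- predict(m, m$test)
    sm <- stratified_metrics(m$test$covas_value, pred$pain_label)
    sev <- sm$recall[sm$stratum == "severe"]
    mld <- sm$recall[sm$stratum == "mild"]
    if (is.na(sev) || is.na(mld)) NA else sev >= mld
  }, logical(1))
  expect_gte(mean(wins, na.rm = TRUE), 0.8)
})

test_that("Bland-Altman agreement matches the worked triple and edge cases", {
  ba <- bland_altman(c(52, 58, 71), c(50, 60, 70))
  expect_equal(round(ba$bias, 3), -0.333)
  expect_equal(ba$loa_high, 3.748, tolerance = 1e-3)
  expect_equal(ba$loa_low, -4.414, tolerance = 1e-3)
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, same$loa_high)
  expect_true(is.na(same$proportional_bias_r))
  shifted <- bland_altman(c(1, 2, 3), c(3, 4, 5))
  expect_equal(shifted$bias, 2)
  expect_equal(shifted$loa_high - shifted$loa_low, 0)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})
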