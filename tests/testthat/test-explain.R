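test_that("exact Shapley values reproduce closed-form attributions", {
  bg <- data.frame(x1 = 0, x2 = 0)
  ex_add <- exact_shapley(function(Z) 2 * Z$x1 + Z$x2, c(x1 = 1, x2 = 1), bg)
  expect_equal(unname(ex_add$phi), c(2, 1))
  ex_mul <- exact_shapley(function(Z) Z$x1 * Z$x2, c(x1 = 1, x2 = 1), bg)
  expect_equal(unname(ex_mul$phi), c(0.5, 0.5))
  ex_const <- exact_shapley(function(Z) rep(7, nrow(Z)), c(x1 = 1, x2 = 1), bg)
  expect_equal(unname(ex_const$phi), c(0, 0))
  expect_equal(ex_const$base_value, 7)
  # enumeration refuses oversized feature sets and points to the tree route
  big <- setNames(as.list(rep(1, 13)), paste0("f", 1:13))
  expect_error(exact_shapley(function(Z) Z$f1, big,
                             as.data.frame(setNames(as.list(rep(0, 13)), paste0("f", 1:13)))),
               "tree_shapley")
})

test_that("Shapley interactions vanish for additive models and decompose phi", {
  bg <- data.frame(x1 = 0, x2 = 0, x3 = 0)
  row <- c(x1 = 1, x2 = 1, x3 = 2)
  add <- function(Z) Z$x1 + 3 * Z$x2 + Z$x3
  ia <- shapley_interaction(add, row, bg)
  expect_lt(max(abs(ia[upper.tri(ia)])), 1e-6)
  mul <- function(Z) Z$x1 * Z$x2 + Z$x3
  im <- shapley_interaction(mul, row, bg)
  expect_gt(abs(im["x1", "x2"]), 0.1)
  phi <- exact_shapley(mul, row, bg)$phi
  expect_equal(rowSums(im), phi, tolerance = 1e-10)
  expect_equal(shapley_interaction(mul, row, bg, pair = c("x1", "x2")),
               im["x1", "x2"])
})

test_that("tree-path Shapley is null for unused features and ranks true signal", {
  set.seed(7)
  n <- 150
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- factor(ifelse(X$x1 > 0, "pain", "no_pain"), levels = c("no_pain", "pain"))
  # force single-feature trees: only x1 is informative and mtry = 3
  rf <- randomForest::randomForest(X, y, ntree = 40, mtry = 3)
  ts <- tree_shapley(rf, X[1:8, ], X[9:20, ])
  expect_gt(mean(abs(ts$phi[, "x1"])), 10 * mean(abs(ts$phi[, "x2"])))
  expect_gt(mean(abs(ts$phi[, "x1"])), 10 * mean(abs(ts$phi[, "x3"])))
})

test_that("Gini importance is normalized and concentrates on the signal", {
  set.seed(8)
  n <- 200
  X <- data.frame(s = rnorm(n), n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  y <- factor(ifelse(X$s > 0, "pain", "no_pain"), levels = c("no_pain", "pain"))
  rf <- randomForest::randomForest(X, y, ntree = 80)
  gi <- gini_importance(rf)
  expect_equal(sum(gi$table$importance_mean), 1)
  expect_gt(gi$table$importance_mean[gi$table$feature == "s"], 0.8)
  # pure-noise labels: near-uniform shares across seeds
  max_shares <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    yn <- factor(sample(c("pain", "no_pain"), n, replace = TRUE),
                 levels = c("no_pain", "pain"))
    max(gini_importance(randomForest::randomForest(X, yn, ntree = 60))$table$importance_mean)
  }, 0)
  expect_true(all(max_shares < 3 / ncol(X)))
})

test_that("permutation importance isolates predictive features", {
  set.seed(9)
  n <- 200
  X <- data.frame(x = rep(c(0, 1), n / 2), junk = rnorm(n))
  y <- factor(ifelse(X$x > 0.5, "pain", "no_pain"), levels = c("no_pain", "pain"))
  fn <- function(Z) factor(ifelse(Z$x > 0.5, "pain", "no_pain"),
                           levels = c("no_pain", "pain"))
  pi <- permutation_importance(fn, X, y, "accuracy", n_repeats = 50, seed = 2)
  tabp <- pi$table
  # a perfectly predictive balanced binary feature loses ~0.5 accuracy
  expect_equal(tabp$importance_mean[tabp$feature == "x"], 0.5, tolerance = 0.1)
  # a feature the model never uses sits within 2 SDs of zero
  junk <- tabp[tabp$feature == "junk", ]
  expect_lte(abs(junk$importance_mean), 2 * max(junk$importance_sd, 1e-12))
  # report prints in "mean ± sd" style
  expect_match(paste(capture.output(print(pi)), collapse = "\n"), "±")
  # metric/model mismatch is an error
  rfreg <- randomForest::randomForest(X, as.numeric(y == "pain") + rnorm(n, 0, 0.01),
                                      ntree = 20)
  expect_error(permutation_importance(rfreg, X, y, "accuracy"), "accuracy")
})

test_that("ICE curves cluster into their generating response families", {
  X <- data.frame(x1 = rep(seq(-2, 2, length.out = 10), 2),
                  grp = rep(c(0, 1), each = 10))
  f <- function(Z) ifelse(Z$grp == 0, Z$x1^2, -Z$x1)
  pd <- partial_dependence_ice(f, X, "x1", grid = seq(-1, 1, by = 0.25))
  ph <- ice_phenotypes(pd, k = 2, seed = 1)
  agree <- max(sum(ph$assignment[X$grp == 0] == 1) + sum(ph$assignment[X$grp == 1] == 2),
               sum(ph$assignment[X$grp == 0] == 2) + sum(ph$assignment[X$grp == 1] == 1))
  expect_gt(agree / nrow(X), 0.9)
  expect_identical(ph$assignment, ice_phenotypes(pd, k = 2, seed = 1)$assignment)
  # identical curves collapse to one effective cluster with zero dispersion
  pd0 <- partial_dependence_ice(function(Z) Z$grp, X, "x1", grid = seq(-1, 1, by = 0.5))
  ph0 <- ice_phenotypes(pd0, k = 2, seed = 1)
  expect_equal(ph0$k_effective, 1)
  expect_equal(ph0$within_dispersion, 0)
  expect_error(ice_phenotypes(pd, k = 100), "exceeds")
  # a model ignoring the feature yields flat PD and ICE
  pdf <- partial_dependence_ice(function(Z) Z$grp * 2, X, "x1")
  expect_equal(diff(range(pdf$pd)), 0)
  expect_true(all(apply(pdf$ice, 1, function(r) diff(range(r))) == 0))
})

test_that("biomarker correlations reflect their algebraic couplings", {
  tab <- strong_feature_table()
  cm <- feature_correlations(tab)
  expect_true(isSymmetric(cm))
  expect_gt(cm["ecg_power", "ecg_rms"], 0.95)
  expect_lt(cm["hr_mean", "ibi_mean"], -0.95)
  expect_equal(unname(cm["sdnn", "sdnn"]), 1)
  expect_true(all(abs(cm[!is.na(cm)]) <= 1 + 1e-12))
})

test_that("a shallow surrogate faithfully mimics a tree-expressible model", {
  set.seed(11)
  X <- data.frame(a = rnorm(300), b = rnorm(300))
  y <- factor(ifelse(X$a > 0.3, "pain", "no_pain"), levels = c("no_pain", "pain"))
  rf <- randomForest::randomForest(X, y, ntree = 60)
  gs <- global_surrogate(rf, X, max_depth = 5, seed = 3)
  expect_equal(gs$fidelity, 1.0)
  expect_match(gs$rules[1], "^IF .* THEN ")
  expect_match(paste(gs$rules, collapse = " "), "a[<>]")
  # fidelity never improves when the depth budget shrinks
  fid <- vapply(1:5, function(s) {
    y2 <- factor(ifelse(X$a + 0.8 * X$b + rnorm(300, 0, 0.3) > 0, "pain", "no_pain"),
                 levels = c("no_pain", "pain"))
    rf2 <- randomForest::randomForest(X, y2, ntree = 60)
    c(global_surrogate(rf2, X, max_depth = 1, seed = s)$fidelity,
      global_surrogate(rf2, X, max_depth = 5, seed = s)$fidelity)
  }, c(0, 0))
  expect_true(all(fid[2, ] >= fid[1, ]))
})
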