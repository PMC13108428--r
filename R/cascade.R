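#' Training configuration for the pain cascade
#'
#' @param test_fraction held-out fraction, in (0, 1); default 0.2.
#' @param n_trees trees per forest (default 100).
#' @param max_depth optional tree depth cap (translated to a leaf-count cap).
#' @param rfe_k number of biomarkers retained by recursive feature
#'   elimination (default 10).
#' @param seed integer seed controlling the split and both forests.
#' @param split_grouping `"by_window"` (stratified row split, default) or
#'   `"by_session"` (whole sessions held out, avoids within-subject leakage).
#' @param threshold classifier probability threshold for calling pain
#'   (default 0.5; a probability exactly at the threshold is called pain).
#' @param regressor_gate `"truth"` trains the intensity regressor on rows
#'   with actual CoVAS > 0 (default); `"classifier"` on rows the fitted
#'   classifier calls pain.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(test_fraction = 0.2, n_trees = 100, max_depth = NULL,
                           rfe_k = 10, seed = 1,
                           split_grouping = c("by_window", "by_session"),
                           threshold = 0.5,
                           regressor_gate = c("truth", "classifier")) {
  check_number(test_fraction, "test_fraction", lower = 1e-9, upper = 1 - 1e-9)
  check_number(rfe_k, "rfe_k", lower = 1)
  structure(list(test_fraction = test_fraction, n_trees = n_trees,
                 max_depth = max_depth, rfe_k = as.integer(rfe_k),
                 seed = as.integer(seed),
                 split_grouping = match.arg(split_grouping),
                 threshold = threshold,
                 regressor_gate = match.arg(regressor_gate)),
            class = "cascade_config")
}

#' Standardize a feature table
#'
#' Fits per-column location/scale on the training data only: missing cells
#' are imputed with the training-column median, then columns are centred and
#' scaled to unit sample SD. Applying a fitted scaler never refits, so test
#' columns generally do not have mean 0 (no leakage). Zero-variance columns
#' get scale 1 with a warning.
#'
#' @param table data.frame of numeric feature columns.
#' @param scaler optional fitted scaler to apply.
#' @return list with `table` (standardized) and `scaler`.
#' @export
standardize <- function(table, scaler = NULL) {
  x <- as.data.frame(table)
  if (is.null(scaler)) {
    med <- vapply(x, function(col) median(col, na.rm = TRUE), 0)
    med[is.na(med)] <- 0
    for (j in seq_along(x)) x[[j]][is.na(x[[j]])] <- med[j]
    mu <- vapply(x, mean, 0)
    sg <- vapply(x, sd, 0)
    zero <- !is.finite(sg) | sg == 0
    if (any(zero)) {
      warnf("standardize: zero-variance column(s) %s; scale set to 1",
            paste(names(x)[zero], collapse = ", "))
      sg[zero] <- 1
    }
    scaler <- structure(list(median = med, mean = mu, sd = sg,
                             features = names(x)), class = "feature_scaler")
  } else {
    miss <- setdiff(scaler$features, names(x))
    if (length(miss)) stopf("standardize: missing feature column(s): %s",
                            paste(miss, collapse = ", "))
    x <- x[scaler$features]
    for (j in seq_along(x)) x[[j]][is.na(x[[j]])] <- scaler$median[j]
  }
  for (j in seq_along(x)) x[[j]] <- (x[[j]] - scaler$mean[j]) / scaler$sd[j]
  list(table = x, scaler = scaler)
}

#' Recursive feature elimination with a random-forest ranker
#'
#' Iteratively fits a forest, drops the feature with the lowest Gini
#' importance (node-impurity decrease), and repeats until `rfe_k` features
#' remain. Deterministic given the seed.
#'
#' @param x data.frame of standardized features.
#' @param y factor (classification) or numeric (regression) target.
#' @param rfe_k number of features to keep.
#' @param n_trees trees per elimination round.
#' @param seed integer seed.
#' @return character vector of retained feature names, ranked by final
#'   importance (most important first).
#' @export
select_features_rfe <- function(x, y, rfe_k, n_trees = 100, seed = 1) {
  feats <- names(x)
  if (rfe_k > length(feats)) stopf("rfe_k (%d) exceeds feature count (%d)", rfe_k, length(feats))
  round_i <- 0
  while (length(feats) > rfe_k) {
    round_i <- round_i + 1
    fit <- with_seed(derive_seed(seed, 100 + round_i),
                     randomForest::randomForest(x = x[feats], y = y, ntree = n_trees))
    imp <- randomForest::importance(fit)[, 1]
    feats <- feats[-which.min(imp)]
  }
  fit <- with_seed(derive_seed(seed, 199),
                   randomForest::randomForest(x = x[feats], y = y, ntree = n_trees))
  feats[order(randomForest::importance(fit)[, 1], decreasing = TRUE)]
}

split_rows <- function(tab, config) {
  if (config$split_grouping == "by_session" && "session" %in% names(tab)) {
    sess <- unique(tab$session)
    n_test <- max(1, round(length(sess) * config$test_fraction))
    test_sess <- with_seed(derive_seed(config$seed, 11), sample(sess, n_test))
    list(train = which(!tab$session %in% test_sess),
         test = which(tab$session %in% test_sess))
  } else {
    test_idx <- integer(0)
    for (lab in unique(tab$covas_label)) {
      rows <- which(tab$covas_label == lab)
      n_test <- max(1, round(length(rows) * config$test_fraction))
      test_idx <- c(test_idx,
                    with_seed(derive_seed(config$seed, 12 + match(lab, c("no_pain", "pain"))),
                              sample(rows, n_test)))
    }
    list(train = setdiff(seq_len(nrow(tab)), test_idx), test = sort(test_idx))
  }
}

#' Fit the dual-layer pain cascade
#'
#' The cascade mirrors clinical reasoning: a random-forest classifier first
#' decides whether pain is present (CoVAS = 0 vs CoVAS > 0); a random-forest
#' regressor then estimates intensity on the 0-100 scale, trained only on
#' pain rows and consulted only when the classifier detects pain. The
#' pipeline is: stratified train/test split, feature standardization fitted
#' on the training split, recursive feature elimination, then both forests.
#'
#' @param feature_table output of [build_feature_table()] (needs the
#'   biomarker columns plus `covas_value` and `covas_label`).
#' @param config a [cascade_config()].
#' @param features candidate feature columns (default [FEATURE_NAMES]
#'   intersected with available columns).
#' @return object of class `pain_cascade`: `scaler`, `selected_features`,
#'   `classifier`, `regressor`, `threshold`, `config`, plus the held-out
#'   `test` rows of `feature_table` and the `train` row indices.
#' @export
fit_cascade <- function(feature_table, config = cascade_config(),
                        features = intersect(FEATURE_NAMES, names(feature_table))) {
  tab <- as.data.frame(feature_table)
  if (!all(c("covas_value", "covas_label") %in% names(tab)))
    stopf("feature_table must contain covas_value and covas_label")
  sp <- split_rows(tab, config)
  train <- tab[sp$train, , drop = FALSE]
  if (length(unique(train$covas_label)) < 2)
    stopf("fit_cascade: training split contains a single class")
  std <- standardize(train[features])
  xtr <- std$table
  ytr <- factor(train$covas_label, levels = c("no_pain", "pain"))
  rfe_k <- min(config$rfe_k, length(features))
  sel <- select_features_rfe(xtr, ytr, rfe_k, n_trees = config$n_trees,
                             seed = config$seed)
  maxnodes <- if (!is.null(config$max_depth)) 2^config$max_depth else NULL
  clf <- with_seed(derive_seed(config$seed, 21),
                   randomForest::randomForest(x = xtr[sel], y = ytr,
                                              ntree = config$n_trees,
                                              maxnodes = maxnodes))
  if (config$regressor_gate == "truth") {
    pain_rows <- train$covas_value > 0
  } else {
    pr <- predict(clf, xtr[sel], type = "prob")[, "pain"]
    pain_rows <- pr >= config$threshold
  }
  if (sum(pain_rows) < 2)
    stopf("fit_cascade: not enough pain rows to train the intensity regressor")
  if (sum(pain_rows) < 10)
    warnf("fit_cascade: only %d pain rows for the regressor", sum(pain_rows))
  reg <- with_seed(derive_seed(config$seed, 22),
                   randomForest::randomForest(x = xtr[pain_rows, sel, drop = FALSE],
                                              y = train$covas_value[pain_rows],
                                              ntree = config$n_trees,
                                              maxnodes = maxnodes))
  structure(list(scaler = std$scaler, selected_features = sel,
                 classifier = clf, regressor = reg,
                 threshold = config$threshold, config = config,
                 features = features,
                 test = tab[sp$test, , drop = FALSE],
                 train_idx = sp$train),
            class = "pain_cascade")
}

#' Predict pain presence and intensity
#'
#' Rows are imputed/scaled with the training scaler, the classifier yields a
#' pain probability, and the intensity regressor is consulted only for rows
#' called pain (probability >= threshold); its output is clipped to
#' \[0, 100\]. Rows called no-pain get intensity exactly 0.
#'
#' @param object a fitted `pain_cascade`.
#' @param newdata data.frame containing the model's selected features.
#' @param ... unused.
#' @return data.frame: `pain_probability`, `pain_label` (factor
#'   no_pain/pain), `intensity`.
#' @export
predict.pain_cascade <- function(object, newdata, ...) {
  miss <- setdiff(object$selected_features, names(newdata))
  if (length(miss))
    stopf("predict.pain_cascade: missing selected feature(s): %s",
          paste(miss, collapse = ", "))
  have <- intersect(object$scaler$features, names(newdata))
  if (!setequal(have, object$scaler$features)) {
    # scale only what the scaler knows; selected features are guaranteed above
    newdata <- newdata[intersect(names(newdata), object$scaler$features)]
    for (f in setdiff(object$scaler$features, names(newdata))) newdata[[f]] <- NA_real_
  }
  xs <- standardize(newdata[object$scaler$features], object$scaler)$table
  prob <- predict(object$classifier, xs[object$selected_features], type = "prob")[, "pain"]
  lab <- factor(ifelse(prob >= object$threshold, "pain", "no_pain"),
                levels = c("no_pain", "pain"))
  intensity <- numeric(length(prob))
  pain <- lab == "pain"
  if (any(pain)) {
    raw <- predict(object$regressor, xs[pain, object$selected_features, drop = FALSE])
    intensity[pain] <- clip(raw, 0, 100)
  }
  data.frame(pain_probability = as.numeric(prob), pain_label = lab,
             intensity = intensity, row.names = NULL)
}

#' @export
print.pain_cascade <- function(x, ...) {
  cat("Dual-layer ECG pain cascade (random forest classifier + conditional regressor)\n")
  cat(sprintf("  selected biomarkers (%d): %s\n", length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  cat(sprintf("  trees: %d | threshold: %g | split: %s | test rows: %d\n",
              x$config$n_trees, x$threshold, x$config$split_grouping, nrow(x$test)))
  invisible(x)
}

#' @export
summary.pain_cascade <- function(object, ...) {
  pred <- predict(object, object$test)
  truth <- factor(object$test$covas_label, levels = c("no_pain", "pain"))
  cls <- classification_metrics(truth, pred$pain_label)
  keep <- object$test$covas_value > 0 & pred$pain_label == "pain"
  reg <- if (sum(keep) >= 3)
    regression_metrics(object$test$covas_value[keep], pred$intensity[keep]) else NULL
  out <- list(model = object, classification = cls, regression = reg,
              n_test = nrow(object$test))
  class(out) <- "summary.pain_cascade"
  out
}

#' @export
print.summary.pain_cascade <- function(x, ...) {
  print(x$model)
  cat(sprintf("Held-out performance (n = %d):\n", x$n_test))
  cat(sprintf("  accuracy %.3f | F1 %.3f | MCC %.3f | kappa %.3f\n",
              x$classification$accuracy, x$classification$f1,
              x$classification$mcc, x$classification$cohen_kappa))
  if (!is.null(x$regression))
    cat(sprintf("  intensity (pain rows): MAE %.2f | RMSE %.2f | R2 %.3f\n",
                x$regression$mae, x$regression$rmse, x$regression$r2))
  invisible(x)
}

#' @export
plot.pain_cascade <- function(x, which = c("importance", "regression"), ...) {
  which <- match.arg(which)
  if (which == "importance") {
    imp <- sort(randomForest::importance(x$classifier)[, 1], decreasing = FALSE)
    graphics::barplot(imp, horiz = TRUE, las = 1,
                      xlab = "Gini importance (node-impurity decrease)",
                      main = "Pain classifier biomarker importance", ...)
  } else {
    pred <- predict(x, x$test)
    keep <- x$test$covas_value > 0 & pred$pain_label == "pain"
    graphics::plot(x$test$covas_value[keep], pred$intensity[keep],
                   xlab = "actual CoVAS", ylab = "predicted intensity",
                   main = "Held-out intensity predictions", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' @export
residuals.pain_cascade <- function(object, ...) {
  pred <- predict(object, object$test)
  keep <- object$test$covas_value > 0 & pred$pain_label == "pain"
  pred$intensity[keep] - object$test$covas_value[keep]
}
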