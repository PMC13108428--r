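# ---- model-function adapters -------------------------------------------

# Turn a supported model into a plain numeric prediction function over a
# data.frame of feature rows. Classifiers yield P(pain); regressors the
# predicted intensity.
as_model_fn <- function(model, positive = "pain") {
  if (is.function(model)) return(model)
  if (inherits(model, "randomForest")) {
    if (model$type == "classification") {
      cls <- if (positive %in% colnames(model$votes)) positive else colnames(model$votes)[2]
      return(function(X) as.numeric(predict(model, as.data.frame(X), type = "prob")[, cls]))
    }
    return(function(X) as.numeric(predict(model, as.data.frame(X))))
  }
  if (inherits(model, "pain_cascade"))
    return(function(X) predict(model, as.data.frame(X))$pain_probability)
  stopf("unsupported model of class %s", paste(class(model), collapse = "/"))
}

shapley_weights <- function(n) {
  # w(s) = s! (n-s-1)! / n! for s = 0..n-1
  exp(lgamma(seq(0, n - 1) + 1) + lgamma(n - seq(0, n - 1)) - lgamma(n + 1))
}

# ---- exact enumeration (the oracle route) ------------------------------

#' Exact Shapley values by full subset enumeration
#'
#' Direct evaluation of the Shapley attribution
#' \deqn{\phi_i = \sum_{S \subseteq N \setminus i} \frac{|S|!\,(|N|-|S|-1)!}{|N|!}\,[f(S \cup i) - f(S)]}
#' where \eqn{f(S)} is the model applied to the row of interest with the
#' features outside \eqn{S} replaced by background values (averaged over the
#' background set). Exponential in the feature count, so capped at
#' `subset_limit` features; larger models go through [tree_shapley()].
#'
#' @param model_fn function mapping a data.frame of rows to numeric
#'   predictions (or a supported model, see details).
#' @param row single-row data.frame (or named vector) to explain.
#' @param background data.frame of background rows defining the reference
#'   distribution.
#' @param subset_limit maximum feature count for enumeration (default 12).
#' @return object of class `shapley_explanation`: `base_value`, named `phi`,
#'   `model_output`. Efficiency (`base_value + sum(phi) = model_output`)
#'   holds to numerical precision.
#' @export
exact_shapley <- function(model_fn, row, background, subset_limit = 12) {
  model_fn <- as_model_fn(model_fn)
  row <- as.data.frame(as.list(row))
  background <- as.data.frame(background)[names(row)]
  n <- ncol(row)
  if (n > subset_limit)
    stopf("exact_shapley: %d features exceeds the enumeration limit (%d); use tree_shapley() or a sampled estimator", n, subset_limit)
  nb <- nrow(background)
  masks <- 0:(2^n - 1)
  inset <- vapply(seq_len(n), function(i) bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0,
                  logical(length(masks)))  # 2^n x n
  x <- as.numeric(row[1, ])
  v <- numeric(length(masks))
  big <- vector("list", nb)
  for (j in seq_len(nb)) {
    b <- as.numeric(background[j, ])
    comp <- matrix(b, nrow = length(masks), ncol = n, byrow = TRUE)
    comp[inset] <- matrix(x, nrow = length(masks), ncol = n, byrow = TRUE)[inset]
    big[[j]] <- comp
  }
  allrows <- as.data.frame(do.call(rbind, big))
  names(allrows) <- names(row)
  preds <- model_fn(allrows)
  v <- rowMeans(matrix(preds, nrow = length(masks), ncol = nb))
  w <- shapley_weights(n)
  sizes <- rowSums(inset)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    without <- which(!inset[, i])
    with_i <- without + 2^(i - 1)
    phi[i] <- sum(w[sizes[without] + 1] * (v[with_i] - v[without]))
  }
  structure(list(base_value = v[1], phi = setNames(phi, names(row)),
                 model_output = v[length(v)]),
            class = "shapley_explanation")
}

#' @export
print.shapley_explanation <- function(x, ...) {
  cat(sprintf("<shapley_explanation> base %.4f -> output %.4f\n",
              x$base_value, x$model_output))
  print(round(x$phi, 4))
  invisible(x)
}

# ---- tree-path route ----------------------------------------------------

# Extract the leaves of one randomForest tree as axis-aligned boxes
# (lo < x <= hi per feature) plus the leaf value. Numeric splits only.
tree_leaf_boxes <- function(rf, k, feat_names, positive = "pain") {
  tr <- randomForest::getTree(rf, k, labelVar = FALSE)
  nfeat <- length(feat_names)
  lo_l <- list(); hi_l <- list(); val <- numeric(0)
  rec <- function(node, lo, hi) {
    if (tr[node, "status"] == -1) {
      lo_l[[length(lo_l) + 1]] <<- lo
      hi_l[[length(hi_l) + 1]] <<- hi
      v <- tr[node, "prediction"]
      if (rf$type == "classification")
        v <- as.numeric(rf$classes[v] == positive)
      val <<- c(val, v)
      return(invisible())
    }
    j <- tr[node, "split var"]; pt <- tr[node, "split point"]
    hi2 <- hi; hi2[j] <- min(hi[j], pt)
    rec(tr[node, "left daughter"], lo, hi2)
    lo2 <- lo; lo2[j] <- max(lo[j], pt)
    rec(tr[node, "right daughter"], lo2, hi)
  }
  rec(1, rep(-Inf, nfeat), rep(Inf, nfeat))
  list(lo = do.call(rbind, lo_l), hi = do.call(rbind, hi_l), val = val)
}

#' Shapley values for a tree ensemble via per-leaf path enumeration
#'
#' Computes the same background-replacement Shapley attribution as
#' [exact_shapley()], but exploits the tree structure instead of enumerating
#' feature subsets: each leaf of each tree is an axis-aligned box, and for a
#' given explained row and background row the features on the leaf's path
#' partition into "must be taken from the row", "must be taken from the
#' background" and "free", which admits a closed-form combinatorial weight.
#' Exact (agrees with the enumeration route to numerical precision) and
#' polynomial in the feature count, so it scales to the full biomarker set.
#'
#' @param model a fitted `randomForest` (classification forests are explained
#'   on the P(pain) vote-fraction scale).
#' @param rows data.frame of rows to explain.
#' @param background data.frame of background rows (reference distribution;
#'   cap it for speed, e.g. a seeded subsample of the training split).
#' @param positive positive class name for classification forests.
#' @return object of class `shapley_set`: `phi` (rows x features matrix),
#'   `base_value`, `model_output` (per row).
#' @export
tree_shapley <- function(model, rows, background, positive = "pain") {
  if (!inherits(model, "randomForest"))
    stopf("tree_shapley supports randomForest tree ensembles")
  feat <- rownames(model$importance)
  rows <- as.data.frame(rows)[feat]
  background <- as.data.frame(background)[feat]
  n <- length(feat)
  nr <- nrow(rows); nb <- nrow(background); nt <- model$ntree
  w <- shapley_weights(n)
  # A[u, q] lookup tables (1-based offsets)
  Apos <- matrix(NA_real_, n + 1, n + 1)
  Aneg <- matrix(NA_real_, n + 1, n + 1)
  for (u in 0:n) for (q in 0:(n - u)) {
    f <- n - u - q
    k <- 0:f
    if (u >= 1) Apos[u + 1, q + 1] <- sum(choose(f, k) * w[u - 1 + k + 1])
    if (q >= 1 && u + f <= n - 1) Aneg[u + 1, q + 1] <- sum(choose(f, k) * w[u + k + 1])
  }
  X <- as.matrix(rows); B <- as.matrix(background)
  phi <- matrix(0, nr, n, dimnames = list(NULL, feat))
  base <- 0; outp <- numeric(nr)
  memb <- function(boxes, v) {
    L <- nrow(boxes$lo)
    vm <- matrix(v, L, n, byrow = TRUE)
    boxes$lo < vm & vm <= boxes$hi
  }
  for (k in seq_len(nt)) {
    boxes <- tree_leaf_boxes(model, k, feat, positive)
    Ax <- lapply(seq_len(nr), function(i) memb(boxes, X[i, ]))
    Cb <- lapply(seq_len(nb), function(j) memb(boxes, B[j, ]))
    val <- boxes$val
    for (j in seq_len(nb)) {
      cj <- Cb[[j]]
      base <- base + sum(val[rowSums(!cj) == 0])
      for (i in seq_len(nr)) {
        ai <- Ax[[i]]
        reach <- rowSums(!ai & !cj) == 0
        if (!any(reach)) next
        pos <- ai & !cj
        neg <- !ai & cj
        u <- rowSums(pos); q <- rowSums(neg)
        cp <- val * Apos[cbind(u + 1, q + 1)] * reach
        cn <- val * Aneg[cbind(u + 1, q + 1)] * reach
        cp[!is.finite(cp)] <- 0; cn[!is.finite(cn)] <- 0
        phi[i, ] <- phi[i, ] + as.numeric(crossprod(pos, cp)) -
                                as.numeric(crossprod(neg, cn))
      }
    }
    for (i in seq_len(nr))
      outp[i] <- outp[i] + sum(val[rowSums(!Ax[[i]]) == 0])
  }
  structure(list(phi = phi / (nt * nb), base_value = base / (nt * nb),
                 model_output = outp / nt, features = feat),
            class = "shapley_set")
}

#' @export
print.shapley_set <- function(x, ...) {
  cat(sprintf("<shapley_set> %d rows x %d features; base value %.4f\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  cat("mean |phi| ranking:\n")
  print(round(sort(colMeans(abs(x$phi)), decreasing = TRUE), 4))
  invisible(x)
}

#' Shapley interaction values
#'
#' Pairwise Shapley interaction indices by subset enumeration over the same
#' background-replacement value function as [exact_shapley()]. For an
#' additive model all off-diagonal interactions are 0; each row of the
#' interaction matrix sums to the feature's Shapley value (the main effect
#' is placed on the diagonal as the residual).
#'
#' @inheritParams exact_shapley
#' @param pair optional length-2 feature-name (or index) vector; when given,
#'   only that interaction value is returned.
#' @return full `n x n` interaction matrix, or a single value when `pair`
#'   is given.
#' @export
shapley_interaction <- function(model_fn, row, background, pair = NULL,
                                subset_limit = 12) {
  model_fn <- as_model_fn(model_fn)
  row <- as.data.frame(as.list(row))
  background <- as.data.frame(background)[names(row)]
  n <- ncol(row)
  if (n > subset_limit)
    stopf("shapley_interaction: %d features exceeds the enumeration limit (%d)", n, subset_limit)
  masks <- 0:(2^n - 1)
  inset <- vapply(seq_len(n), function(i) bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0,
                  logical(length(masks)))
  x <- as.numeric(row[1, ]); nb <- nrow(background)
  big <- vector("list", nb)
  for (j in seq_len(nb)) {
    comp <- matrix(as.numeric(background[j, ]), nrow = length(masks), ncol = n, byrow = TRUE)
    comp[inset] <- matrix(x, nrow = length(masks), ncol = n, byrow = TRUE)[inset]
    big[[j]] <- comp
  }
  allrows <- as.data.frame(do.call(rbind, big)); names(allrows) <- names(row)
  v <- rowMeans(matrix(model_fn(allrows), nrow = length(masks), ncol = nb))
  sizes <- rowSums(inset)
  # pairwise weights: |S|! (n-|S|-2)! / (2 (n-1)!)
  wp <- exp(lgamma(seq(0, n - 2) + 1) + lgamma(n - 1 - seq(0, n - 2)) - lgamma(n)) / 2
  inter <- matrix(0, n, n, dimnames = list(names(row), names(row)))
  for (i in seq_len(n - 1)) for (jj in seq(i + 1, n)) {
    without <- which(!inset[, i] & !inset[, jj])
    d <- v[without + 2^(i - 1) + 2^(jj - 1)] - v[without + 2^(i - 1)] -
         v[without + 2^(jj - 1)] + v[without]
    inter[i, jj] <- inter[jj, i] <- sum(wp[sizes[without] + 1] * d)
  }
  phi <- exact_shapley(model_fn, row, background, subset_limit)$phi
  diag(inter) <- phi - rowSums(inter)
  if (!is.null(pair)) return(inter[pair[1], pair[2]])
  inter
}

# ---- importance reports -------------------------------------------------

new_importance_report <- function(df, method, metric_name, n_repeats = NA) {
  structure(list(table = df, method = method, metric_name = metric_name,
                 n_repeats = n_repeats),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, digits = 4, ...) {
  cat(sprintf("<importance_report> method: %s (%s)%s\n", x$method, x$metric_name,
              if (!is.na(x$n_repeats)) sprintf(", %d repeats", x$n_repeats) else ""))
  tab <- x$table[order(-x$table$importance_mean), ]
  for (r in seq_len(nrow(tab))) {
    if (!is.na(tab$importance_sd[r]))
      cat(sprintf("  %s: %.*f ± %.*f\n", tab$feature[r], digits,
                  tab$importance_mean[r], digits, tab$importance_sd[r]))
    else cat(sprintf("  %s: %.*f\n", tab$feature[r], digits, tab$importance_mean[r]))
  }
  invisible(x)
}

#' Gini (mean decrease in impurity) importance
#'
#' Total node-impurity reduction attributable to each feature across the
#' ensemble, normalized to sum to 1.
#'
#' @param model a fitted `randomForest`, or a `pain_cascade` (then `layer`
#'   picks which forest).
#' @param layer `"classifier"` or `"regressor"` for cascade models.
#' @return an `importance_report`.
#' @export
gini_importance <- function(model, layer = c("classifier", "regressor")) {
  layer <- match.arg(layer)
  if (inherits(model, "pain_cascade")) model <- model[[layer]]
  if (!inherits(model, "randomForest")) stopf("gini_importance needs a randomForest")
  imp <- randomForest::importance(model)[, 1]
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  new_importance_report(
    data.frame(feature = names(imp), importance_mean = as.numeric(imp),
               importance_sd = NA_real_, stringsAsFactors = FALSE),
    "gini", "impurity_decrease")
}

#' Permutation feature importance
#'
#' Shuffles each feature in turn (others held fixed) and measures the drop
#' in model performance — accuracy for classification, R^2 for regression —
#' repeated `n_repeats` times with different shuffles for statistical
#' stability (reported as mean and SD of the drop).
#'
#' @param model `randomForest`, `pain_cascade`, or a prediction function.
#' @param X evaluation feature rows (permutation happens within this split).
#' @param y true labels (factor) or numeric target.
#' @param metric `"accuracy"` or `"r2"`; must match the model task.
#' @param n_repeats shuffle repeats per feature (default 100).
#' @param seed integer seed.
#' @return an `importance_report` with per-feature mean and SD.
#' @export
permutation_importance <- function(model, X, y, metric = c("accuracy", "r2"),
                                   n_repeats = 100, seed = 1) {
  metric <- match.arg(metric)
  X <- as.data.frame(X)
  if (inherits(model, "randomForest")) {
    if (model$type == "classification" && metric != "accuracy")
      stopf("metric 'r2' does not apply to a classification forest")
    if (model$type == "regression" && metric != "r2")
      stopf("metric 'accuracy' does not apply to a regression forest")
    pf <- function(Z) predict(model, Z)
  } else if (inherits(model, "pain_cascade")) {
    if (metric != "accuracy") stopf("cascade permutation importance uses the pain label (accuracy)")
    pf <- function(Z) predict(model, Z)$pain_label
  } else if (is.function(model)) pf <- model
  else stopf("unsupported model")
  score <- function(pred) {
    if (metric == "accuracy") mean(as.character(pred) == as.character(y))
    else 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  baseline <- score(pf(X))
  feats <- names(X)
  res <- with_seed(derive_seed(seed, 31), {
    lapply(feats, function(f) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        Z <- X
        Z[[f]] <- Z[[f]][sample.int(nrow(Z))]
        baseline - score(pf(Z))
      }, 0)
      c(mean(drops), if (n_repeats > 1) sd(drops) else NA_real_)
    })
  })
  df <- data.frame(feature = feats,
                   importance_mean = vapply(res, `[`, 0, 1),
                   importance_sd = vapply(res, `[`, 0, 2),
                   stringsAsFactors = FALSE)
  rep <- new_importance_report(df, "permutation", metric, n_repeats)
  rep$baseline <- baseline
  rep
}

# ---- PDP / ICE ----------------------------------------------------------

#' Partial dependence and ICE curves for one feature
#'
#' The ICE matrix holds the model's prediction for every instance with the
#' target feature swept over a grid; the partial dependence curve is the
#' exact columnwise mean of the ICE curves (empirical marginalization over
#' the other features).
#'
#' @param model model or prediction function (see [as_model_fn()] rules).
#' @param X data.frame of instances.
#' @param feature feature name to sweep.
#' @param grid explicit grid values; default `n_grid` points between the
#'   1st and 99th percentile of the observed feature.
#' @param n_grid grid size (default 50).
#' @return object of class `pdp_result`: `feature`, `grid`, `pd`, `ice`.
#' @export
partial_dependence_ice <- function(model, X, feature, grid = NULL, n_grid = 50) {
  model_fn <- as_model_fn(model)
  X <- as.data.frame(X)
  if (!feature %in% names(X)) stopf("feature '%s' not in X", feature)
  if (!is.numeric(X[[feature]])) stopf("partial dependence supports numeric features only")
  if (is.null(grid)) {
    qs <- quantile(X[[feature]], c(0.01, 0.99), na.rm = TRUE)
    grid <- if (qs[1] == qs[2]) qs[1] else seq(qs[1], qs[2], length.out = n_grid)
  }
  n <- nrow(X); g <- length(grid)
  big <- X[rep(seq_len(n), times = g), , drop = FALSE]
  big[[feature]] <- rep(grid, each = n)
  ice <- matrix(model_fn(big), nrow = n, ncol = g)
  structure(list(feature = feature, grid = as.numeric(grid),
                 pd = colMeans(ice), ice = ice),
            class = "pdp_result")
}

#' @export
plot.pdp_result <- function(x, max_ice = 50, ...) {
  idx <- seq_len(min(max_ice, nrow(x$ice)))
  graphics::matplot(x$grid, t(x$ice[idx, , drop = FALSE]), type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    xlab = x$feature, ylab = "prediction",
                    main = sprintf("PDP/ICE: %s", x$feature), ...)
  graphics::lines(x$grid, x$pd, lwd = 3, lty = 2, col = "navy")
  invisible(x)
}

#' Cluster ICE curves into response phenotypes
#'
#' Centres each ICE curve at its leftmost grid value (so shapes, not
#' offsets, are clustered) and applies seeded k-means. Intended to surface
#' distinct pain-response phenotypes among instances.
#'
#' @param pdp a `pdp_result`.
#' @param k number of phenotypes (default 3).
#' @param seed integer seed.
#' @return list: `assignment` (per instance), `k_effective`,
#'   `within_dispersion` (total within-cluster sum of squares), `centers`.
#' @export
ice_phenotypes <- function(pdp, k = 3, seed = 1) {
  curves <- pdp$ice - pdp$ice[, 1]
  n <- nrow(curves)
  if (k > n) stopf("ice_phenotypes: k (%d) exceeds instance count (%d)", k, n)
  uniq <- unique(curves)
  if (nrow(uniq) < k) {
    key <- apply(curves, 1, paste, collapse = ",")
    assignment <- as.integer(factor(key, levels = unique(key)))
    return(list(assignment = assignment, k_effective = nrow(uniq),
                within_dispersion = 0, centers = uniq))
  }
  km <- with_seed(derive_seed(seed, 41), kmeans(curves, centers = k, nstart = 10))
  list(assignment = km$cluster, k_effective = k,
       within_dispersion = km$tot.withinss, centers = km$centers)
}

# ---- correlation & surrogate -------------------------------------------

#' Pearson correlation matrix of the biomarker table
#'
#' Pairwise-complete Pearson correlations over the numeric feature columns;
#' zero-variance columns are flagged undefined (NA row/column).
#'
#' @param feature_table data.frame (label/metadata columns are ignored).
#' @param features columns to include (default: those in [FEATURE_NAMES]).
#' @return symmetric correlation matrix.
#' @export
feature_correlations <- function(feature_table,
                                 features = intersect(FEATURE_NAMES, names(feature_table))) {
  x <- feature_table[features]
  if (nrow(x) < 3) stopf("feature_correlations: need at least 3 rows")
  suppressWarnings(cor(x, use = "pairwise.complete.obs"))
}

#' Global surrogate: a shallow decision tree mimicking the model
#'
#' Fits a depth-limited CART tree to the model's own predictions, reports
#' fidelity (agreement with the model on held-out rows) and exports the
#' leaves as human-readable IF/AND/THEN rules.
#'
#' @param model model or prediction function; classification surrogates are
#'   fit to the predicted label, regression surrogates to the numeric output.
#' @param X data.frame of instances.
#' @param max_depth tree depth cap (default 5).
#' @param test_fraction held-out fraction for the fidelity score.
#' @param seed integer seed for the fidelity split.
#' @return object of class `global_surrogate`: `tree` (rpart), `fidelity`,
#'   `rules` (character), `task`.
#' @export
global_surrogate <- function(model, X, max_depth = 5, test_fraction = 0.3, seed = 1) {
  X <- as.data.frame(X)
  if (inherits(model, "randomForest") && model$type == "classification") {
    yhat <- predict(model, X)
    task <- "classification"
  } else if (inherits(model, "pain_cascade")) {
    yhat <- predict(model, X)$pain_label
    task <- "classification"
  } else {
    fn <- as_model_fn(model)
    yhat <- fn(X)
    task <- if (is.factor(yhat)) "classification" else "regression"
  }
  d <- cbind(X, .y = yhat)
  idx <- with_seed(derive_seed(seed, 51),
                   sample(nrow(d), max(1, round(nrow(d) * test_fraction))))
  fitd <- d[-idx, , drop = FALSE]; held <- d[idx, , drop = FALSE]
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0)
  method <- if (task == "classification") "class" else "anova"
  tree <- rpart::rpart(.y ~ ., data = fitd, method = method, control = ctrl)
  pred_h <- predict(tree, held, type = if (task == "classification") "class" else "vector")
  fidelity <- if (task == "classification")
    mean(as.character(pred_h) == as.character(held$.y))
  else {
    sst <- sum((held$.y - mean(held$.y))^2)
    if (sst == 0) as.numeric(all(abs(pred_h - held$.y) < 1e-12))
    else 1 - sum((pred_h - held$.y)^2) / sst
  }
  structure(list(tree = tree, fidelity = fidelity,
                 rules = surrogate_rules(tree, task), task = task),
            class = "global_surrogate")
}

# Export rpart leaves as "IF ... AND ... THEN ..." rule strings.
surrogate_rules <- function(tree, task) {
  fr <- tree$frame
  ids <- as.integer(rownames(fr))
  labs <- labels(tree)
  leaves <- which(fr$var == "<leaf>")
  out <- character(0)
  for (li in leaves) {
    node <- ids[li]
    conds <- character(0)
    nd <- node
    while (nd > 1) {
      conds <- c(labs[match(nd, ids)], conds)
      nd <- nd %/% 2
    }
    cond_txt <- if (length(conds)) paste(conds, collapse = " AND ") else "TRUE"
    if (task == "classification") {
      lev <- attr(tree, "ylevels")[fr$yval[li]]
      prob <- max(fr$yval2[li, , drop = TRUE][seq_len(length(attr(tree, "ylevels"))) +
                                                1 + length(attr(tree, "ylevels"))])
      out <- c(out, sprintf("IF %s THEN %s (prob %.2f)", cond_txt, lev, prob))
    } else {
      out <- c(out, sprintf("IF %s THEN prediction = %.3f", cond_txt, fr$yval[li]))
    }
  }
  out
}

#' @export
print.global_surrogate <- function(x, ...) {
  cat(sprintf("<global_surrogate> %s tree, fidelity %.3f, %d rules\n",
              x$task, x$fidelity, length(x$rules)))
  for (r in head(x$rules, 10)) cat(" ", r, "\n")
  if (length(x$rules) > 10) cat(sprintf("  ... and %d more\n", length(x$rules) - 10))
  invisible(x)
}
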