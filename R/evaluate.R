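as_binary <- function(x, positive = "pain") {
  if (is.logical(x)) return(x)
  as.character(x) == positive
}

#' Binary classification metrics (pain = positive class)
#'
#' Standard definitions from the 2x2 confusion table. Ratios with a zero
#' denominator are flagged missing (NA), never reported as 0.
#'
#' @param true_labels,pred_labels vectors coercible to pain/no-pain
#'   (factor/character with level `"pain"`, or logical).
#' @return object of class `classification_report`: accuracy, precision,
#'   recall (sensitivity), specificity, f1, mcc, cohen_kappa, confusion.
#' @export
classification_metrics <- function(true_labels, pred_labels) {
  if (length(true_labels) == 0) stopf("classification_metrics: empty input")
  if (length(true_labels) != length(pred_labels)) stopf("length mismatch")
  t <- as_binary(true_labels); p <- as_binary(pred_labels)
  tp <- sum(t & p); fn <- sum(t & !p); tn <- sum(!t & !p); fp <- sum(!t & p)
  n <- tp + fn + tn + fp
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  specificity <- rat(tn, tn + fp)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  conf <- matrix(c(tn, fn, fp, tp), 2, 2,
                 dimnames = list(pred = c("no_pain", "pain"),
                                 true = c("no_pain", "pain")))
  structure(list(accuracy = po, precision = precision, recall = recall,
                 specificity = specificity, f1 = f1, mcc = mcc,
                 cohen_kappa = kappa, confusion = conf, n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | specificity %.4f\n",
              x$accuracy, x$precision, x$recall, x$specificity))
  cat(sprintf("F1 %.4f | MCC %.4f | kappa %.4f (n = %d)\n",
              x$f1, x$mcc, x$cohen_kappa, x$n))
  invisible(x)
}

#' ROC / PR area under the curve with a bootstrap CI
#'
#' ROC AUC is the rank statistic (Mann-Whitney with half credit for ties);
#' PR AUC is average precision. The confidence interval is a stratified
#' percentile bootstrap (classes resampled separately).
#'
#' @param true_labels binary labels (pain positive).
#' @param scores classifier scores (higher = more pain-like).
#' @param curve `"roc"` or `"pr"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @param level CI level (default 0.95).
#' @return list: `auc`, `lo`, `hi`, `curve`.
#' @export
auc_with_ci <- function(true_labels, scores, curve = c("roc", "pr"),
                        n_boot = 2000, seed = 1, level = 0.95) {
  curve <- match.arg(curve)
  t <- as_binary(true_labels)
  if (all(t) || !any(t)) stopf("auc_with_ci: both classes must be present")
  auc1 <- function(t, s) {
    if (curve == "roc") {
      r <- rank(s)
      np <- sum(t); nn <- sum(!t)
      (sum(r[t]) - np * (np + 1) / 2) / (np * nn)
    } else {
      o <- order(-s)
      tt <- t[o]
      prec <- cumsum(tt) / seq_along(tt)
      sum(prec[tt]) / sum(tt)   # average precision
    }
  }
  est <- auc1(t, scores)
  pos <- which(t); neg <- which(!t)
  boots <- with_seed(derive_seed(seed, 61), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      auc1(t[idx], scores[idx])
    }, 0)
  })
  alpha <- (1 - level) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(auc = est, lo = qs[1], hi = qs[2], curve = curve)
}

#' Regression (pain intensity) metrics
#'
#' MAE, RMSE, MAPE, R^2, mean bias, residual SD and the share of
#' predictions within ±5/±10/±15 CoVAS units (boundaries included).
#' MAPE is flagged missing when any actual value is 0.
#'
#' @param actual,predicted numeric vectors on the 0-100 CoVAS scale.
#' @return object of class `regression_report`.
#' @export
regression_metrics <- function(actual, predicted) {
  if (length(actual) == 0 || length(actual) != length(predicted))
    stopf("regression_metrics: empty input or length mismatch")
  e <- predicted - actual
  mape <- if (any(actual == 0)) NA_real_ else 100 * mean(abs(e) / actual)
  sst <- sum((actual - mean(actual))^2)
  r2 <- if (sst > 0) 1 - sum(e^2) / sst else NA_real_
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), mape_pct = mape,
                 r2 = r2, mean_bias = mean(e),
                 resid_sd = if (length(e) > 1) sd(e) else NA_real_,
                 pct_within_5 = 100 * mean(abs(e) <= 5),
                 pct_within_10 = 100 * mean(abs(e) <= 10),
                 pct_within_15 = 100 * mean(abs(e) <= 15),
                 n = length(e)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("MAE %.3f | RMSE %.3f | MAPE %.1f%% | R2 %.3f | bias %.3f\n",
              x$mae, x$rmse, x$mape_pct, x$r2, x$mean_bias))
  cat(sprintf("within ±5: %.1f%% | ±10: %.1f%% | ±15: %.1f%% (n = %d)\n",
              x$pct_within_5, x$pct_within_10, x$pct_within_15, x$n))
  invisible(x)
}

#' Performance stratified by pain-severity category
#'
#' Strata follow the clinical convention: no pain (CoVAS = 0), mild (0, 30],
#' moderate (30, 70], severe (70, 100]. For each pain stratum, recall is the
#' share of its windows called pain; precision contrasts the stratum's true
#' positives against false alarms from the no-pain stratum. The no-pain row
#' reports specificity. Empty strata give missing-flag rows.
#'
#' @param actual_covas numeric actual CoVAS values.
#' @param predictions predicted pain labels, or numeric intensities (then
#'   pain is called when intensity > 0).
#' @param breaks upper edges of the pain strata (default `c(30, 70, 100)`).
#' @return data.frame, one row per stratum: `stratum`, `n`, `precision`,
#'   `recall`, `specificity`.
#' @export
stratified_metrics <- function(actual_covas, predictions,
                               breaks = c(30, 70, 100)) {
  if (is.numeric(predictions)) pred_pain <- predictions > 0
  else pred_pain <- as_binary(predictions)
  stopifnot(length(actual_covas) == length(pred_pain))
  edges <- c(0, breaks)
  strat_names <- c("no_pain", "mild", "moderate", "severe")[seq_len(length(breaks) + 1)]
  stratum <- character(length(actual_covas))
  stratum[actual_covas == 0] <- "no_pain"
  for (k in seq_along(breaks))
    stratum[actual_covas > edges[k] & actual_covas <= edges[k + 1]] <- strat_names[k + 1]
  fp_nopain <- sum(stratum == "no_pain" & pred_pain)
  rows <- lapply(strat_names, function(s) {
    idx <- stratum == s
    n <- sum(idx)
    if (n == 0)
      return(data.frame(stratum = s, n = 0L, precision = NA_real_,
                        recall = NA_real_, specificity = NA_real_))
    if (s == "no_pain") {
      data.frame(stratum = s, n = n, precision = NA_real_, recall = NA_real_,
                 specificity = mean(!pred_pain[idx]))
    } else {
      tp <- sum(pred_pain[idx])
      prec <- if (tp + fp_nopain > 0) tp / (tp + fp_nopain) else NA_real_
      data.frame(stratum = s, n = n, precision = prec, recall = tp / n,
                 specificity = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Bland-Altman agreement analysis
#'
#' Agreement between predicted and actual pain intensity: bias is the mean
#' of the differences (predicted minus actual), the limits of agreement are
#' bias ± 1.96 x the sample SD of the differences, and proportional bias is
#' the Pearson correlation between pairwise means and differences.
#'
#' @param actual,predicted numeric vectors, length >= 3.
#' @return object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `pct_within_loa`, `proportional_bias_r`, plus the `means`/`diffs` used.
#' @export
bland_altman <- function(actual, predicted) {
  if (length(actual) < 3) stopf("bland_altman: need at least 3 pairs")
  if (length(actual) != length(predicted)) stopf("length mismatch")
  d <- predicted - actual
  m <- (predicted + actual) / 2
  bias <- mean(d)
  s <- sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  r <- if (s > 0 && sd(m) > 0) cor(m, d) else NA_real_
  structure(list(bias = bias, loa_low = loa_low, loa_high = loa_high,
                 pct_within_loa = 100 * mean(d >= loa_low & d <= loa_high),
                 proportional_bias_r = r, means = m, diffs = d,
                 sd_diff = s, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("bias %.3f | LoA [%.3f, %.3f] | %.1f%% within LoA | proportional r %.3f (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$pct_within_loa,
              x$proportional_bias_r, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of predicted and actual",
                 ylab = "predicted - actual", main = "Bland-Altman agreement", ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2, col = "red")
  invisible(x)
}
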