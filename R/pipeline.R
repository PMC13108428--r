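#' End-to-end experiment configuration
#'
#' One object holding every knob of a full run: generation, segmentation,
#' feature flags, cascade training and explanation settings. Every
#' stochastic stage derives its own seed deterministically from the single
#' global seed.
#'
#' @param n_sessions synthetic sessions to generate (default 3).
#' @param protocol a [protocol_spec()].
#' @param effect an [autonomic_effect()].
#' @param fs_hz sampling rate (default 250).
#' @param window_mode `"stimulus_aligned"` or `"fixed_length"`.
#' @param label_reduce `"mean"` or `"max"` CoVAS reduction.
#' @param cascade a [cascade_config()] (its seed is overridden by `seed`).
#' @param n_background background rows for Shapley (default 25).
#' @param n_shap_rows rows to explain with Shapley (default 20).
#' @param n_perm_repeats permutation-importance repeats (default 100).
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_sessions = 3, protocol = protocol_spec(),
                       effect = autonomic_effect(), fs_hz = 250,
                       window_mode = "stimulus_aligned", label_reduce = "mean",
                       cascade = cascade_config(), n_background = 25,
                       n_shap_rows = 20, n_perm_repeats = 100, seed = 1) {
  cascade$seed <- as.integer(seed)
  structure(list(n_sessions = n_sessions, protocol = protocol, effect = effect,
                 fs_hz = fs_hz, window_mode = window_mode,
                 label_reduce = label_reduce, cascade = cascade,
                 n_background = n_background, n_shap_rows = n_shap_rows,
                 n_perm_repeats = n_perm_repeats, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline: simulate, segment, extract, train, explain, evaluate
#'
#' Generates `n_sessions` synthetic pain sessions, segments them into
#' labeled windows, extracts the biomarker battery, fits the dual-layer
#' cascade, evaluates it on the held-out split (classification metrics with
#' AUC, intensity regression metrics, severity-stratified performance,
#' Bland-Altman agreement) and computes the explanation bundle (Gini and
#' permutation importance, tree-path Shapley on a subsample, PDP/ICE for the
#' top biomarker, global surrogate rules). Artifacts are written under
#' `out_dir`; metric JSON output is byte-identical across runs with the same
#' config and seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing files.
#' @return (invisibly) list with `feature_table`, `model`, `prediction`,
#'   `reports`, `explanations`, `paths`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL) {
  stage <- "simulate"
  result <- tryCatch({
    sessions <- lapply(seq_len(config$n_sessions), function(i)
      generate_session(config$protocol, config$effect, fs_hz = config$fs_hz,
                       seed = derive_seed(config$seed, 1000 + i)))
    stage <- "segment"
    wsets <- lapply(seq_along(sessions), function(i)
      suppressWarnings(segment_windows(sessions[[i]], mode = config$window_mode,
                                       label_reduce = config$label_reduce,
                                       session_id = sprintf("s%02d", i))))
    stage <- "extract"
    tab <- suppressMessages(build_feature_table(wsets))
    stage <- "train"
    model <- suppressWarnings(fit_cascade(tab, config$cascade))
    stage <- "evaluate"
    pred <- predict(model, model$test)
    truth_lab <- factor(model$test$covas_label, levels = c("no_pain", "pain"))
    cls <- classification_metrics(truth_lab, pred$pain_label)
    auc <- auc_with_ci(truth_lab, pred$pain_probability, "roc",
                       n_boot = 500, seed = derive_seed(config$seed, 71))
    keep <- model$test$covas_value > 0 & pred$pain_label == "pain"
    reg <- if (sum(keep) >= 3)
      regression_metrics(model$test$covas_value[keep], pred$intensity[keep]) else NULL
    ba <- if (sum(keep) >= 3)
      bland_altman(model$test$covas_value[keep], pred$intensity[keep]) else NULL
    strat <- stratified_metrics(model$test$covas_value, pred$pain_label)
    stage <- "explain"
    train_rows <- standardize(tab[model$train_idx, model$features], model$scaler)$table
    bg <- train_rows[with_seed(derive_seed(config$seed, 72),
                               sample(nrow(train_rows), min(config$n_background, nrow(train_rows)))),
                     model$selected_features, drop = FALSE]
    test_std <- standardize(model$test[model$features], model$scaler)$table
    xrows <- test_std[with_seed(derive_seed(config$seed, 73),
                                sample(nrow(test_std), min(config$n_shap_rows, nrow(test_std)))),
                      model$selected_features, drop = FALSE]
    shap <- tree_shapley(model$classifier, xrows, bg)
    gini <- gini_importance(model$classifier)
    perm <- permutation_importance(model$classifier,
                                   test_std[model$selected_features],
                                   truth_lab, "accuracy",
                                   n_repeats = config$n_perm_repeats,
                                   seed = derive_seed(config$seed, 74))
    top_feat <- gini$table$feature[which.max(gini$table$importance_mean)]
    pdp <- partial_dependence_ice(model$classifier, xrows, top_feat, n_grid = 25)
    surr <- global_surrogate(model$classifier, train_rows[model$selected_features],
                             max_depth = 5, seed = derive_seed(config$seed, 75))
    corr <- feature_correlations(tab)
    list(sessions = sessions, feature_table = tab, model = model,
         prediction = pred,
         reports = list(classification = cls, auc_roc = auc, regression = reg,
                        bland_altman = ba, stratified = strat),
         explanations = list(shapley = shap, gini = gini, permutation = perm,
                             pdp = pdp, surrogate = surr, correlations = corr))
  }, error = function(e) {
    stopf("run_experiment failed at stage '%s': %s", stage, conditionMessage(e))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      features = file.path(out_dir, "features.csv"),
      metrics = file.path(out_dir, "metrics.json"),
      importance = file.path(out_dir, "importance.csv"),
      shapley = file.path(out_dir, "shapley.csv"),
      rules = file.path(out_dir, "surrogate_rules.txt"),
      manifest = file.path(out_dir, "manifest.json"))
    write.csv(result$feature_table, paths$features, row.names = FALSE)
    rep <- result$reports
    metrics <- list(
      classification = rep$classification[c("accuracy", "precision", "recall",
                                            "specificity", "f1", "mcc", "cohen_kappa")],
      auc_roc = rep$auc_roc[c("auc", "lo", "hi")],
      regression = if (!is.null(rep$regression))
        rep$regression[c("mae", "rmse", "mape_pct", "r2", "mean_bias", "resid_sd",
                         "pct_within_5", "pct_within_10", "pct_within_15")],
      bland_altman = if (!is.null(rep$bland_altman))
        rep$bland_altman[c("bias", "loa_low", "loa_high", "pct_within_loa",
                           "proportional_bias_r")],
      stratified = rep$stratified)
    writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = 10,
                                na = "null", dataframe = "rows"), paths$metrics)
    imp <- rbind(cbind(method = "gini", result$explanations$gini$table),
                 cbind(method = "permutation", result$explanations$permutation$table))
    write.csv(imp, paths$importance, row.names = FALSE)
    sh <- result$explanations$shapley
    shl <- data.frame(row = rep(seq_len(nrow(sh$phi)), ncol(sh$phi)),
                      feature = rep(colnames(sh$phi), each = nrow(sh$phi)),
                      phi = as.numeric(sh$phi))
    write.csv(shl, paths$shapley, row.names = FALSE)
    writeLines(result$explanations$surrogate$rules, paths$rules)
    manifest <- list(
      package_version = as.character(utils::packageVersion("cardiopain")),
      seed = config$seed,
      config = list(n_sessions = config$n_sessions,
                    window_mode = config$window_mode,
                    label_reduce = config$label_reduce,
                    cascade = unclass(config$cascade),
                    effect = unclass(config$effect),
                    protocol = unclass(config$protocol)),
      metrics_md5 = unname(tools::md5sum(paths$metrics)))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                na = "null"), paths$manifest)
    result$paths <- paths
  }
  invisible(result)
}

#' Ingest externally recorded sessions from a directory
#'
#' Reads every `*.csv` session trace (header `t_s,ecg_mv,covas,
#' stimulus_level`, JSON sidecar with `fs_hz`) under `path`; sessions whose
#' sampling rate differs from `fs_target` are resampled to it, with a note.
#'
#' @param path directory of session CSVs.
#' @param fs_target common analysis rate (default 250 Hz).
#' @return list of `session_record`s.
#' @export
ingest_sessions <- function(path, fs_target = 250) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stopf("ingest_sessions: no CSV files under %s", path)
  lapply(files, function(f) {
    rec <- read_session_csv(f)
    if (abs(rec$fs_hz - fs_target) > 1e-9) {
      message(sprintf("ingest_sessions: %s at %g Hz, resampling to %g Hz",
                      basename(f), rec$fs_hz, fs_target))
      rec$ecg <- suppressWarnings(resample_trace(rec$ecg, rec$fs_hz, fs_target))
      rec$covas <- suppressWarnings(resample_trace(rec$covas, rec$fs_hz, fs_target,
                                                   method = "constant"))
      rec$stimulus_level <- as.integer(suppressWarnings(
        resample_trace(rec$stimulus_level, rec$fs_hz, fs_target, method = "constant")))
      rec$fs_hz <- fs_target
      rec$t_s <- (seq_along(rec$ecg) - 1) / fs_target
      rec$covas <- clip(rec$covas, 0, 100)
      validate_session(rec)
    }
    rec
  })
}
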