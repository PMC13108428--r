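# Shared fixtures, built once per test run. Sessions are generated in code;
# nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

session_battery <- function(effect = autonomic_effect(), seed0 = 7000, n = 3) {
  key <- sprintf("tab_%d", seed0)
  if (is.null(.fixtures[[key]])) {
    tabs <- lapply(seq_len(n), function(i) {
      s <- generate_session(effect = effect, seed = seed0 + i)
      ws <- suppressWarnings(segment_windows(s, session_id = sprintf("s%d", seed0 + i)))
      suppressMessages(build_feature_table(ws))
    })
    .fixtures[[key]] <- do.call(rbind, tabs)
  }
  .fixtures[[key]]
}

strong_feature_table <- function() session_battery(autonomic_effect(), 7000)
null_feature_table <- function() session_battery(null_effect(), 7100)

strong_model <- function() {
  if (is.null(.fixtures$strong_model))
    .fixtures$strong_model <- suppressWarnings(
      fit_cascade(strong_feature_table(), cascade_config(seed = 71)))
  .fixtures$strong_model
}

# Feature table with a known informative subset: real biomarker axes from
# generated sessions plus pure-noise columns.
panel_with_noise <- function(informative = c("hr_mean", "ecg_rms"),
                             n_noise = 6, seed = 99) {
  tab <- strong_feature_table()
  out <- tab[, c(informative, "covas_value", "covas_label")]
  set.seed(seed)
  for (k in seq_len(n_noise)) out[[sprintf("noise%d", k)]] <- rnorm(nrow(out))
  out
}

# tiny protocol for property tests that need many sessions
tiny_protocol <- function() protocol_spec(n_levels = 2, reps_per_level = 3,
                                          rest_range_s = c(12, 16),
                                          level_temps_c = c(41, 48))
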