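#' Resample a trace to a new sampling rate
#'
#' Cubic-spline interpolation onto the target time grid. Output length is
#' `round(n * fs_out / fs_in)`. Downsampling emits a warning because content
#' above the new Nyquist frequency would alias; the pipeline's traces are
#' band-limited well below it.
#'
#' @param values numeric trace.
#' @param fs_in,fs_out sampling rates (Hz), both > 0.
#' @param method `"spline"` (default) or `"constant"` for step-valued traces
#'   such as stimulus markers.
#' @return numeric trace at `fs_out`.
#' @export
resample_trace <- function(values, fs_in, fs_out, method = c("spline", "constant")) {
  check_number(fs_in, "fs_in", lower = 1e-12)
  check_number(fs_out, "fs_out", lower = 1e-12)
  method <- match.arg(method)
  if (fs_in == fs_out) return(values)
  if (fs_out < fs_in)
    warnf("resample_trace: downsampling %g -> %g Hz; content above %g Hz would alias",
          fs_in, fs_out, fs_out / 2)
  n_out <- round(length(values) * fs_out / fs_in)
  t_in <- (seq_along(values) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  if (method == "constant")
    approx(t_in, values, xout = t_out, method = "constant", rule = 2)$y
  else
    spline(t_in, values, xout = t_out, method = "natural")$y
}

#' Synchronize independently clocked traces onto a common time base
#'
#' Each trace is a list with `values`, `fs_hz` and `t0_s` (start time on the
#' shared wall clock). All traces are cropped to their overlapping interval
#' and resampled to `fs_out`. ECG is spline-interpolated; CoVAS and stimulus
#' markers are step-interpolated so that rest periods keep their exact zeros.
#'
#' @param ecg,covas,stimulus_level lists with `values`, `fs_hz`, `t0_s`.
#' @param fs_out common output rate (default 250 Hz).
#' @return a `session_record` on the common grid.
#' @export
synchronize_session <- function(ecg, covas, stimulus_level, fs_out = 250) {
  traces <- list(ecg = ecg, covas = covas, stimulus_level = stimulus_level)
  t0 <- vapply(traces, function(tr) tr$t0_s, 0)
  t1 <- vapply(traces, function(tr) tr$t0_s + (length(tr$values) - 1) / tr$fs_hz, 0)
  lo <- max(t0); hi <- min(t1)
  if (hi <= lo) stopf("synchronize_session: traces have no temporal overlap")
  t_out <- seq(lo, hi, by = 1 / fs_out)
  interp1 <- function(tr, method) {
    t_in <- tr$t0_s + (seq_along(tr$values) - 1) / tr$fs_hz
    if (method == "constant")
      approx(t_in, tr$values, xout = t_out, method = "constant", rule = 2)$y
    else spline(t_in, tr$values, xout = t_out, method = "natural")$y
  }
  rec <- structure(list(ecg = interp1(ecg, "spline"), fs_hz = fs_out,
                        covas = clip(interp1(covas, "constant"), 0, 100),
                        stimulus_level = as.integer(round(interp1(stimulus_level, "constant"))),
                        t_s = t_out - lo, seed = NA_integer_,
                        truth = NULL, protocol = NULL, stim_onsets_s = NULL),
                   class = "session_record")
  validate_session(rec)
}

#' Reduce a window's CoVAS trace to a value and a binary label
#'
#' The label rule is the study's: no pain iff the reduced CoVAS equals 0,
#' pain iff it is greater than 0.
#'
#' @param covas_values CoVAS samples over the window (0-100).
#' @param reduce `"mean"` (default) or `"max"`.
#' @return list with `covas_value` and `covas_label` (`"pain"`/`"no_pain"`).
#' @export
label_window <- function(covas_values, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  if (length(covas_values) == 0) stopf("label_window: empty CoVAS trace")
  if (any(covas_values < 0 | covas_values > 100))
    stopf("label_window: CoVAS outside [0, 100]")
  v <- if (reduce == "mean") mean(covas_values) else max(covas_values)
  list(covas_value = v, covas_label = if (v > 0) "pain" else "no_pain")
}

#' Segment a session into labeled analysis windows
#'
#' `"stimulus_aligned"` (the default analysis unit) cuts one window per
#' stimulus onset covering the stimulus duration, plus one equal-length
#' baseline window ending at each onset; a stimulus too close to the record
#' start loses its baseline window with a warning. `"fixed_length"` cuts
#' consecutive windows of `window_len` samples with the given stride.
#'
#' @param record a `session_record`.
#' @param mode `"stimulus_aligned"` or `"fixed_length"`.
#' @param window_len window length in samples for fixed mode (default 1000).
#' @param stride stride in samples for fixed mode (default `window_len`).
#' @param stim_duration_s stimulus window length in seconds; defaults to the
#'   record's protocol (10 s when absent).
#' @param label_reduce CoVAS reduction rule, `"mean"` or `"max"`.
#' @param session_id provenance tag carried into downstream tables.
#' @return object of class `window_set`: list of windows, each with
#'   `samples`, `fs_hz`, `kind`, `covas_value`, `covas_label`,
#'   `stimulus_level`, `t_start_s`.
#' @export
segment_windows <- function(record, mode = c("stimulus_aligned", "fixed_length"),
                            window_len = 1000, stride = window_len,
                            stim_duration_s = NULL,
                            label_reduce = "mean", session_id = "s1") {
  mode <- match.arg(mode)
  validate_session(record)
  fs <- record$fs_hz
  n <- length(record$ecg)
  mk <- function(i0, i1, kind, level, t0) {
    lab <- label_window(record$covas[i0:i1], reduce = label_reduce)
    list(samples = record$ecg[i0:i1], fs_hz = fs, kind = kind,
         covas_value = lab$covas_value, covas_label = lab$covas_label,
         stimulus_level = level, t_start_s = t0)
  }
  windows <- list()
  if (mode == "stimulus_aligned") {
    if (is.null(stim_duration_s))
      stim_duration_s <- if (!is.null(record$protocol)) record$protocol$stim_duration_s else 10
    wlen <- round(stim_duration_s * fs)
    lvl <- record$stimulus_level
    onsets <- which(diff(c(0L, lvl > 0L)) == 1L)
    dropped <- 0L
    for (o in onsets) {
      i1 <- o + wlen - 1
      if (i1 > n) next
      windows[[length(windows) + 1]] <-
        mk(o, i1, "stimulus", lvl[o], (o - 1) / fs)
      if (o - wlen >= 1) {
        windows[[length(windows) + 1]] <-
          mk(o - wlen, o - 1, "baseline", 0L, (o - wlen - 1) / fs)
      } else dropped <- dropped + 1L
    }
    if (dropped > 0)
      warnf("segment_windows: dropped %d baseline window(s) too close to record start", dropped)
  } else {
    starts <- seq(1, n - window_len + 1, by = stride)
    for (s in starts) {
      i1 <- s + window_len - 1
      lvl_mode <- as.integer(names(which.max(table(record$stimulus_level[s:i1]))))
      windows[[length(windows) + 1]] <-
        mk(s, i1, if (lvl_mode > 0) "stimulus" else "baseline", lvl_mode, (s - 1) / fs)
    }
  }
  structure(list(windows = windows,
                 provenance = list(session = session_id, mode = mode,
                                   fs_hz = fs, label_reduce = label_reduce)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  kinds <- vapply(x$windows, `[[`, "", "kind")
  labs <- vapply(x$windows, `[[`, "", "covas_label")
  cat(sprintf("<window_set> %d windows (%d stimulus, %d baseline); %d pain / %d no-pain [%s]\n",
              length(x$windows), sum(kinds == "stimulus"), sum(kinds == "baseline"),
              sum(labs == "pain"), sum(labs == "no_pain"), x$provenance$mode))
  invisible(x)
}
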