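#' Canonical biomarker column names
#'
#' Order of the feature columns produced by [build_feature_table()].
#' @export
FEATURE_NAMES <- c("ecg_rms", "ecg_peak_to_peak", "ecg_power", "ecg_kurtosis",
                   "ecg_skewness", "decg_rms", "rr_mean", "rr_std", "rr_rmssd",
                   "pnn50", "sdnn", "vlf_power", "lf_power", "hf_power",
                   "lf_hf", "tri_index", "tinn", "hr_mean", "ibi_mean")

#' Detect R peaks in an ECG window
#'
#' Pan-Tompkins-style detector: 5-25 Hz band-pass, differentiation, squaring
#' and a 150 ms moving-average energy envelope, followed by an adaptive
#' threshold with a 250 ms refractory period. Peak times are refined on the
#' raw signal. Offset (baseline wander DC) invariant by construction.
#'
#' @param samples ECG voltages (mV).
#' @param fs_hz sampling rate, >= 100 Hz.
#' @return object of class `rr_series`: `r_peak_times_s` (s), `rr_ms`
#'   (successive differences in ms) and `missing` (TRUE when fewer than two
#'   beats could be found, in which case HRV features are flagged missing
#'   rather than zero).
#' @export
detect_r_peaks <- function(samples, fs_hz) {
  check_number(fs_hz, "fs_hz", lower = 100)
  if (length(samples) < 2 * fs_hz)
    stopf("detect_r_peaks: window must be at least 2 s long")
  empty <- structure(list(r_peak_times_s = numeric(0), rr_ms = numeric(0),
                          missing = TRUE), class = "rr_series")
  if (sd(samples) == 0) return(empty)
  bp <- signal::butter(3, c(5, 25) / (fs_hz / 2), type = "pass")
  f <- signal::filtfilt(bp, samples - mean(samples))
  e <- c(0, diff(f) * fs_hz)^2
  k <- max(3, round(0.150 * fs_hz))
  env <- stats::filter(e, rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  thr <- 0.20 * quantile(env, 0.995)
  if (thr <= 0) return(empty)
  n <- length(env)
  cand <- which(env > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[env[cand] >= env[cand - 1] & env[cand] >= env[cand + 1]]
  if (length(cand) == 0) return(empty)
  # refractory: accept in time order, keep the stronger of conflicting peaks
  refr <- round(0.250 * fs_hz)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] > refr) keep <- c(keep, i)
    else if (env[i] > env[keep[length(keep)]]) keep[length(keep)] <- i
  }
  # refine to the raw-signal maximum near each envelope peak
  half <- round(0.075 * fs_hz)
  peaks <- vapply(keep, function(i) {
    i0 <- max(1, i - half); i1 <- min(n, i + half)
    as.integer(i0 - 1 + which.max(samples[i0:i1]))
  }, 0L)
  peaks <- sort(unique(peaks))
  if (length(peaks) >= 2) {
    ok <- c(TRUE, diff(peaks) > refr)
    peaks <- peaks[ok]
  }
  if (length(peaks) < 2) return(empty)
  tt <- (peaks - 1) / fs_hz
  structure(list(r_peak_times_s = tt, rr_ms = diff(tt) * 1000, missing = FALSE),
            class = "rr_series")
}

#' Basic ECG window statistics
#'
#' RMS and power are computed on the raw (uncentered) signal; kurtosis is the
#' Fisher excess and skewness the standardized third moment, both in
#' uncorrected population form. A zero-variance window gets missing moments.
#'
#' @param samples ECG voltages (mV), length >= 2.
#' @return named list: `ecg_rms`, `ecg_peak_to_peak`, `ecg_power`,
#'   `ecg_kurtosis`, `ecg_skewness`.
#' @export
ecg_statistics <- function(samples) {
  if (length(samples) < 2) stopf("ecg_statistics: need at least 2 samples")
  m <- mean(samples)
  m2 <- mean((samples - m)^2)
  out <- list(ecg_rms = sqrt(mean(samples^2)),
              ecg_peak_to_peak = max(samples) - min(samples),
              ecg_power = mean(samples^2),
              ecg_kurtosis = NA_real_, ecg_skewness = NA_real_)
  if (m2 > 0) {
    out$ecg_kurtosis <- mean((samples - m)^4) / m2^2 - 3
    out$ecg_skewness <- mean((samples - m)^3) / m2^1.5
  }
  out
}

#' RMS of the first derivative of a trace
#'
#' First difference scaled by the sampling rate (units mV/s), then RMS;
#' captures the rate of change of the cardiac waveform.
#'
#' @param samples trace (mV); @param fs_hz sampling rate (Hz).
#' @return `decg_rms` (mV/s).
#' @export
derivative_statistics <- function(samples, fs_hz) {
  if (length(samples) < 2) stopf("derivative_statistics: need at least 2 samples")
  d <- diff(samples) * fs_hz
  list(decg_rms = sqrt(mean(d^2)))
}

#' Time-domain HRV measures
#'
#' @param rr_ms RR intervals in milliseconds.
#' @return list: `rr_mean` (ms), `rr_std` (sample SD, i.e. SDNN, ms),
#'   `rr_rmssd` (ms), `pnn50` (% of successive differences strictly greater
#'   than 50 ms). Insufficient beats give missing values, not zeros.
#' @export
hrv_time_domain <- function(rr_ms) {
  out <- list(rr_mean = NA_real_, rr_std = NA_real_, rr_rmssd = NA_real_,
              pnn50 = NA_real_)
  n <- length(rr_ms)
  if (n >= 1) out$rr_mean <- mean(rr_ms)
  if (n >= 3) {
    d <- diff(rr_ms)
    out$rr_std <- sd(rr_ms)
    out$rr_rmssd <- sqrt(mean(d^2))
    out$pnn50 <- 100 * sum(abs(d) > 50) / (n - 1)
  }
  out
}

#' Frequency-domain HRV via Welch's method
#'
#' The unevenly sampled RR tachogram is cubic-spline interpolated to an
#' even 4 Hz grid, mean-removed, and analysed with Welch's method (60-s
#' Hann segments, 50\% overlap; the segment shrinks with a warning on short
#' records). Band powers are trapezoidal integrals of the PSD over the VLF
#' (0.003-0.04 Hz), LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands.
#'
#' @param rr an `rr_series`, or a numeric vector of RR intervals in ms (then
#'   assumed contiguous).
#' @param band_edges named list of `c(lo, hi)` Hz per band.
#' @param interp_fs_hz tachogram interpolation rate (default 4 Hz).
#' @param seg_len_s Welch segment length (default 60 s).
#' @return object of class `spectral_bands`: `vlf_power`, `lf_power`,
#'   `hf_power` (ms^2), `lf_hf`.
#' @export
hrv_frequency_domain <- function(rr,
                                 band_edges = list(vlf = c(0.003, 0.04),
                                                   lf = c(0.04, 0.15),
                                                   hf = c(0.15, 0.4)),
                                 interp_fs_hz = 4, seg_len_s = 60) {
  if (inherits(rr, "rr_series")) {
    if (isTRUE(rr$missing) || length(rr$rr_ms) < 4)
      return(structure(list(vlf_power = NA_real_, lf_power = NA_real_,
                            hf_power = NA_real_, lf_hf = NA_real_),
                       class = "spectral_bands"))
    t_beat <- rr$r_peak_times_s[-1]
    y <- rr$rr_ms
  } else {
    y <- rr
    if (length(y) < 4)
      return(structure(list(vlf_power = NA_real_, lf_power = NA_real_,
                            hf_power = NA_real_, lf_hf = NA_real_),
                       class = "spectral_bands"))
    t_beat <- cumsum(y) / 1000
  }
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / interp_fs_hz)
  tach <- spline(t_beat, y, xout = grid, method = "natural")$y
  tach <- tach - mean(tach)
  ps <- welch_psd(tach, interp_fs_hz, seg_len_s = seg_len_s)
  pw <- lapply(band_edges, function(b) band_power(ps$freq_hz, ps$psd, b[1], b[2]))
  lf_hf <- if (pw$hf > 0) pw$lf / pw$hf else NA_real_
  structure(list(vlf_power = pw$vlf, lf_power = pw$lf, hf_power = pw$hf,
                 lf_hf = lf_hf), class = "spectral_bands")
}

#' Geometric HRV: triangular index and TINN
#'
#' RR-interval histogram with the conventional 1000/128 ~ 7.8125 ms bin
#' width. The triangular index is the total beat count divided by the modal
#' bin height; TINN is the base width (ms) of the least-squares best-fit
#' triangle to the histogram (apex fixed at the modal bin).
#'
#' @param rr_ms RR intervals (ms).
#' @param bin_width_ms histogram bin width (default 1000/128 ms).
#' @return list: `tri_index`, `tinn` (ms); attribute `low_confidence` set
#'   when fewer than 20 intervals are available.
#' @export
hrv_geometric <- function(rr_ms, bin_width_ms = 1000 / 128) {
  if (length(rr_ms) < 2)
    return(structure(list(tri_index = NA_real_, tinn = NA_real_),
                     low_confidence = TRUE))
  bw <- bin_width_ms
  lo <- floor(min(rr_ms) / bw) * bw
  breaks <- seq(lo, max(rr_ms) + bw, by = bw)
  cnt <- as.numeric(table(cut(rr_ms, breaks, right = FALSE, include.lowest = TRUE)))
  tri <- length(rr_ms) / max(cnt)
  nz <- which(cnt > 0)
  if (length(nz) == 1) {
    out <- list(tri_index = tri, tinn = bw)
  } else {
    # least-squares triangle: apex at modal bin centre, search base endpoints
    centers <- breaks[-length(breaks)] + bw / 2
    pad <- 25
    centers <- c(seq(centers[1] - pad * bw, centers[1] - bw, by = bw), centers,
                 seq(centers[length(centers)] + bw, centers[length(centers)] + pad * bw, by = bw))
    cnt_p <- c(numeric(pad), cnt, numeric(pad))
    mode_i <- pad + which.max(cnt)
    xm <- centers[mode_i]; ym <- max(cnt)
    best <- c(Inf, NA, NA)
    for (ni in seq(1, mode_i - 1)) {
      for (mi in seq(mode_i + 1, length(centers))) {
        q <- numeric(length(centers))
        left <- seq(ni, mode_i)
        q[left] <- ym * (centers[left] - centers[ni]) / (xm - centers[ni])
        right <- seq(mode_i, mi)
        q[right] <- ym * (centers[mi] - centers[right]) / (centers[mi] - xm)
        sse <- sum((cnt_p - q)^2)
        if (sse < best[1]) best <- c(sse, centers[ni], centers[mi])
      }
    }
    out <- list(tri_index = tri, tinn = best[3] - best[2])
  }
  structure(out, low_confidence = length(rr_ms) < 20)
}

# Full biomarker battery for one window; NA-filled when beats are missing.
window_features <- function(w) {
  st <- ecg_statistics(w$samples)
  dv <- derivative_statistics(w$samples, w$fs_hz)
  rr <- detect_r_peaks(w$samples, w$fs_hz)
  td <- hrv_time_domain(if (rr$missing) numeric(0) else rr$rr_ms)
  fd <- hrv_frequency_domain(rr)
  ge <- if (rr$missing) list(tri_index = NA_real_, tinn = NA_real_)
        else hrv_geometric(rr$rr_ms)
  hr <- if (is.na(td$rr_mean)) NA_real_ else 60000 / td$rr_mean
  c(st, dv, td["rr_mean"], td["rr_std"], td["rr_rmssd"], td["pnn50"],
    list(sdnn = td$rr_std),
    list(vlf_power = fd$vlf_power, lf_power = fd$lf_power,
         hf_power = fd$hf_power, lf_hf = fd$lf_hf),
    list(tri_index = ge$tri_index, tinn = ge$tinn,
         hr_mean = hr, ibi_mean = td$rr_mean))
}

#' Build the biomarker feature table for a window set
#'
#' One row per window: the full biomarker battery (see [FEATURE_NAMES])
#' followed by `covas_value`, `covas_label` and window metadata. Windows with
#' unusable ECG keep their row with missing HRV cells; a summary count of
#' such windows is reported via `message()`.
#'
#' @param window_set a `window_set`, or a list of them (rows are pooled and
#'   tagged with their session of origin).
#' @return `data.frame`, one row per window.
#' @export
build_feature_table <- function(window_set) {
  sets <- if (inherits(window_set, "window_set")) list(window_set) else window_set
  rows <- list()
  n_missing <- 0L
  for (ws in sets) {
    sid <- ws$provenance$session
    for (w in ws$windows) {
      fv <- suppressWarnings(window_features(w))
      if (is.na(fv$rr_mean)) n_missing <- n_missing + 1L
      rows[[length(rows) + 1]] <- data.frame(
        as.data.frame(fv[FEATURE_NAMES]),
        covas_value = w$covas_value, covas_label = w$covas_label,
        kind = w$kind, stimulus_level = w$stimulus_level,
        t_start_s = w$t_start_s, session = sid,
        stringsAsFactors = FALSE)
    }
  }
  if (n_missing > 0)
    message(sprintf("build_feature_table: %d window(s) had unusable ECG; HRV cells set missing", n_missing))
  do.call(rbind, rows)
}
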