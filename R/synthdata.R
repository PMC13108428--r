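#' Thermal-stimulation protocol specification
#'
#' Describes the session layout of a tonic heat-pain experiment: a set of
#' thermode temperature levels, each applied repeatedly for a fixed stimulus
#' duration with randomized order and uniformly drawn rest periods in between.
#' Defaults follow the standard paradigm of five temperature levels, each
#' applied eight times for 10 s with 20-30 s rests, from a 32 degree C
#' non-painful baseline.
#'
#' @param n_levels number of stimulus temperature levels.
#' @param reps_per_level applications per level.
#' @param stim_duration_s stimulus duration in seconds.
#' @param rest_range_s length-2 vector, min/max rest between stimuli (s).
#' @param baseline_temp_c thermode baseline temperature (degrees C).
#' @param level_temps_c temperatures of the levels (degrees C), lowest first.
#' @param randomized_order shuffle the stimulus order?
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_levels = 5, reps_per_level = 8, stim_duration_s = 10,
                          rest_range_s = c(20, 30), baseline_temp_c = 32,
                          level_temps_c = c(41, 43, 45, 46.5, 48),
                          randomized_order = TRUE) {
  check_number(stim_duration_s, "stim_duration_s", lower = 1e-9)
  check_number(reps_per_level, "reps_per_level", lower = 1)
  if (length(rest_range_s) != 2 || rest_range_s[1] > rest_range_s[2] || rest_range_s[1] < 0)
    stopf("rest_range_s must be (min, max) with 0 <= min <= max")
  if (length(level_temps_c) != n_levels)
    stopf("level_temps_c must have length n_levels (%d), got %d", n_levels, length(level_temps_c))
  structure(list(n_levels = as.integer(n_levels),
                 reps_per_level = as.integer(reps_per_level),
                 stim_duration_s = stim_duration_s,
                 rest_range_s = rest_range_s,
                 baseline_temp_c = baseline_temp_c,
                 level_temps_c = level_temps_c,
                 randomized_order = isTRUE(randomized_order)),
            class = "protocol_spec")
}

#' Ground-truth autonomic pain response
#'
#' Tunable effect sizes encoding how nociceptive input modulates cardiac
#' dynamics in the generator: heart rate rises, beat-to-beat variability
#' (SDNN) is suppressed and ECG amplitude increases in proportion to the
#' momentary pain rating, while sympathovagal balance (LF/HF) shifts upward.
#' These are the recoverable ground truth against which the feature and
#' explanation layers are validated.
#'
#' @param baseline_hr_bpm resting heart rate (beats/min), in (30, 200).
#' @param hr_gain_bpm_per_pain_unit HR increase per CoVAS unit (bpm).
#' @param baseline_sdnn_ms resting SDNN (ms).
#' @param sdnn_suppression_frac_at_max_pain fraction of SDNN lost at CoVAS 100,
#'   in \[0, 1).
#' @param amplitude_gain_frac_at_max_pain fractional ECG amplitude increase at
#'   CoVAS 100.
#' @param lfhf_baseline resting LF/HF ratio.
#' @param lfhf_gain LF/HF increase at CoVAS 100.
#' @param covas_noise_sd SD of the truncated Gaussian noise on the CoVAS
#'   plateau of each stimulus (CoVAS units).
#' @param hr_drift_sd_bpm SD of the slow (VLF-band) stimulus-independent
#'   heart-rate drift over the session (bpm). Emulates thermoregulatory and
#'   posture-related wander so that rest and mild-pain windows genuinely
#'   overlap, as they do in recorded data.
#' @param amp_drift_sd_frac SD of the slow fractional drift of ECG amplitude
#'   (electrode and respiration effects).
#' @return object of class `autonomic_effect`.
#' @export
autonomic_effect <- function(baseline_hr_bpm = 70, hr_gain_bpm_per_pain_unit = 0.25,
                             baseline_sdnn_ms = 50,
                             sdnn_suppression_frac_at_max_pain = 0.5,
                             amplitude_gain_frac_at_max_pain = 0.3,
                             lfhf_baseline = 1.5, lfhf_gain = 1.5,
                             covas_noise_sd = 3,
                             hr_drift_sd_bpm = 3, amp_drift_sd_frac = 0.05) {
  check_number(baseline_hr_bpm, "baseline_hr_bpm", lower = 30 + 1e-9, upper = 200 - 1e-9)
  check_number(sdnn_suppression_frac_at_max_pain, "sdnn_suppression_frac_at_max_pain",
               lower = 0, upper = 1 - 1e-9)
  check_number(baseline_sdnn_ms, "baseline_sdnn_ms", lower = 0)
  structure(list(baseline_hr_bpm = baseline_hr_bpm,
                 hr_gain_bpm_per_pain_unit = hr_gain_bpm_per_pain_unit,
                 baseline_sdnn_ms = baseline_sdnn_ms,
                 sdnn_suppression_frac_at_max_pain = sdnn_suppression_frac_at_max_pain,
                 amplitude_gain_frac_at_max_pain = amplitude_gain_frac_at_max_pain,
                 lfhf_baseline = lfhf_baseline, lfhf_gain = lfhf_gain,
                 covas_noise_sd = covas_noise_sd,
                 hr_drift_sd_bpm = hr_drift_sd_bpm,
                 amp_drift_sd_frac = amp_drift_sd_frac),
            class = "autonomic_effect")
}

#' Null autonomic effect (all pain gains zero)
#' @inheritParams autonomic_effect
#' @return `autonomic_effect` with every pain-modulated gain set to 0.
#' @export
null_effect <- function(baseline_hr_bpm = 70, baseline_sdnn_ms = 50,
                        lfhf_baseline = 1.5) {
  autonomic_effect(baseline_hr_bpm = baseline_hr_bpm,
                   hr_gain_bpm_per_pain_unit = 0,
                   baseline_sdnn_ms = baseline_sdnn_ms,
                   sdnn_suppression_frac_at_max_pain = 0,
                   amplitude_gain_frac_at_max_pain = 0,
                   lfhf_baseline = lfhf_baseline, lfhf_gain = 0,
                   covas_noise_sd = 0)
}

# Band-limited unit-variance modulation via spectral synthesis: Gaussian
# spectral lobes with random phases, inverse FFT. Returns a series sampled at
# fs_mod whose power sits where the lobes are placed.
spectral_modulation <- function(n, fs_mod, lobes) {
  if (n < 8) return(numeric(n))
  freq <- seq(0, n - 1) * fs_mod / n
  half <- freq[seq_len(floor(n / 2) + 1)]
  gain2 <- numeric(length(half))
  for (lb in lobes)   # peak scaled by 1/bw so lobe *power* matches lb$power
    gain2 <- gain2 + lb$power / lb$bw * exp(-(half - lb$f0)^2 / (2 * lb$bw^2))
  amp <- sqrt(gain2)
  ph <- runif(length(half), 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  spec[1] <- 0
  full <- complex(length.out = n)
  full[seq_along(half)] <- spec
  if (n %% 2 == 0) full[length(half)] <- complex(real = amp[length(half)], imaginary = 0)
  idx <- seq(2, ceiling(n / 2))
  full[n + 2 - idx] <- Conj(full[idx])
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Generate an RR-interval tachogram with controlled SDNN and LF/HF
#'
#' Spectral synthesis of beat-to-beat variability: one low-frequency lobe
#' (~0.1 Hz) and one high-frequency lobe (~0.25 Hz) with powers in the
#' requested LF/HF ratio, total variance scaled so the SDNN of the resulting
#' RR series matches `sdnn_target_ms`. Beat times are accumulated until the
#' requested duration is filled.
#'
#' @param duration_s record length (s), > 0.
#' @param mean_hr_bpm mean heart rate (beats/min), in (30, 200).
#' @param sdnn_target_ms target SDNN (ms), >= 0; 0 gives a metronomic rhythm.
#' @param lf_hf_ratio ratio of LF to HF lobe power.
#' @param seed integer seed; output is deterministic given the seed.
#' @param lf_hz,hf_hz lobe centre frequencies (Hz).
#' @return numeric vector of RR intervals in seconds.
#' @export
generate_rr_tachogram <- function(duration_s, mean_hr_bpm, sdnn_target_ms,
                                  lf_hf_ratio = 1, seed = 1,
                                  lf_hz = 0.10, hf_hz = 0.25) {
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(mean_hr_bpm, "mean_hr_bpm", lower = 30 + 1e-9, upper = 200 - 1e-9)
  check_number(sdnn_target_ms, "sdnn_target_ms", lower = 0)
  mean_rr <- 60 / mean_hr_bpm
  if (sdnn_target_ms == 0)
    return(rep(mean_rr, floor(duration_s / mean_rr + 1e-9)))
  fs_mod <- 4
  n <- max(64, ceiling(duration_s * fs_mod))
  pl <- lf_hf_ratio / (1 + lf_hf_ratio)
  ph <- 1 / (1 + lf_hf_ratio)
  m <- with_seed(seed, spectral_modulation(n, fs_mod,
        list(list(f0 = lf_hz, bw = 0.02, power = pl),
             list(f0 = hf_hz, bw = 0.03, power = ph))))
  m <- m * sdnn_target_ms / 1000
  tm <- seq(0, n - 1) / fs_mod
  rr <- numeric(0)
  t <- 0
  while (TRUE) {
    mod <- approx(tm, m, xout = min(t, tm[n]), rule = 2)$y
    iv <- max(0.25, mean_rr + mod)
    if (t + iv > duration_s + 1e-9) break
    rr <- c(rr, iv)
    t <- t + iv
  }
  rr
}

default_morphology <- function() {
  # PQRST as Gaussian bumps relative to the R peak (seconds, mV)
  list(offset_s = c(P = -0.200, Q = -0.035, R = 0, S = 0.035, T = 0.300),
       width_s  = c(P = 0.045, Q = 0.012, R = 0.022, S = 0.015, T = 0.070),
       amp_mv   = c(P = 0.12, Q = -0.12, R = 1.00, S = -0.25, T = 0.35))
}

#' Synthesize an ECG voltage trace from RR intervals
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) placed relative
#' to the R peak at the start of its RR interval; the whole beat waveform is
#' scaled by `amplitude_scale` (scalar, or one value per beat), and white
#' Gaussian noise is added.
#'
#' @param rr_intervals RR intervals in seconds, all > 0.2 s.
#' @param fs_hz sampling rate (>= 100 Hz).
#' @param amplitude_scale scalar or per-beat multiplicative amplitude.
#' @param morphology list with `offset_s`, `width_s`, `amp_mv` (see
#'   [default_morphology()]).
#' @param noise_sd_mv SD of additive white noise (mV).
#' @param seed integer seed for the noise.
#' @return numeric vector of voltages (mV), length `round(sum(rr) * fs_hz)`.
#' @export
synthesize_ecg <- function(rr_intervals, fs_hz, amplitude_scale = 1,
                           morphology = default_morphology(),
                           noise_sd_mv = 0, seed = 1) {
  if (length(rr_intervals) == 0) return(numeric(0))
  check_number(fs_hz, "fs_hz", lower = 100)
  if (any(rr_intervals <= 0.2))
    stopf("synthesize_ecg: RR interval <= 0.2 s is unphysiological")
  nb <- length(rr_intervals)
  scale <- rep_len(amplitude_scale, nb)
  r_times <- cumsum(c(0, rr_intervals))[seq_len(nb)] + 0.35 * rr_intervals[1]
  n <- round(sum(rr_intervals) * fs_hz)
  x <- numeric(n)
  for (b in seq_len(nb)) {
    for (w in seq_along(morphology$amp_mv)) {
      mu <- r_times[b] + morphology$offset_s[w]
      sg <- morphology$width_s[w]
      i0 <- max(1, floor((mu - 4 * sg) * fs_hz) + 1)
      i1 <- min(n, ceiling((mu + 4 * sg) * fs_hz) + 1)
      if (i0 > i1) next
      tt <- (seq(i0, i1) - 1) / fs_hz
      x[i0:i1] <- x[i0:i1] + scale[b] * morphology$amp_mv[w] * exp(-(tt - mu)^2 / (2 * sg^2))
    }
  }
  if (noise_sd_mv > 0) x <- x + with_seed(seed, rnorm(n, 0, noise_sd_mv))
  x
}

#' Generate a complete synthetic pain session
#'
#' Lays out the stimulation schedule of `protocol` (randomized level order,
#' uniform rests), assigns each stimulus a CoVAS plateau from a linear
#' level-to-rating map with truncated Gaussian noise, and synthesizes an ECG
#' whose instantaneous heart rate, SDNN, LF/HF balance and beat amplitude are
#' modulated by the momentary CoVAS value according to `effect`. CoVAS is
#' exactly 0 whenever no stimulus is applied and during applications of a
#' level mapped to rating 0.
#'
#' @param protocol a [protocol_spec()].
#' @param effect an [autonomic_effect()]; stored in the output as `truth`.
#' @param fs_hz sampling rate of the session traces (default 250 Hz).
#' @param seed integer master seed; the session is deterministic given it.
#' @param covas_targets plateau rating per level (0-100), nondecreasing,
#'   length `n_levels`. Default spans no-pain through mild/moderate/severe.
#' @param ecg_noise_sd_mv measurement noise on the ECG channel (mV).
#' @return object of class `session_record` with elements `ecg`, `fs_hz`,
#'   `covas`, `stimulus_level`, `t_s`, `seed`, `truth`, `protocol`,
#'   `stim_onsets_s`, `stim_covas`.
#' @export
generate_session <- function(protocol = protocol_spec(),
                             effect = autonomic_effect(), fs_hz = 250,
                             seed = 1, covas_targets = c(0, 15, 35, 60, 85),
                             ecg_noise_sd_mv = 0.02) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(effect, "autonomic_effect"))
  if (length(covas_targets) != protocol$n_levels)
    stopf("covas_targets must have length n_levels (%d)", protocol$n_levels)
  if (is.unsorted(covas_targets))
    stopf("covas_targets must be nondecreasing in level")
  n_stim <- protocol$n_levels * protocol$reps_per_level
  order_seed <- derive_seed(seed, 1)
  levels_seq <- rep(seq_len(protocol$n_levels), each = protocol$reps_per_level)
  if (protocol$randomized_order)
    levels_seq <- with_seed(order_seed, sample(levels_seq))
  rests <- with_seed(derive_seed(seed, 2),
                     runif(n_stim + 1, protocol$rest_range_s[1], protocol$rest_range_s[2]))
  covas_noise <- with_seed(derive_seed(seed, 3), rnorm(n_stim, 0, effect$covas_noise_sd))
  stim_covas <- covas_targets[levels_seq]
  stim_covas <- ifelse(stim_covas == 0, 0, clip(stim_covas + covas_noise, 0, 100))

  onsets <- numeric(n_stim)
  t <- rests[1]
  for (i in seq_len(n_stim)) {
    onsets[i] <- t
    t <- t + protocol$stim_duration_s + rests[i + 1]
  }
  duration <- t

  # per-sample CoVAS and stimulus-level traces
  n <- round(duration * fs_hz)
  t_s <- (seq_len(n) - 1) / fs_hz
  covas <- numeric(n)
  stim_lvl <- integer(n)
  for (i in seq_len(n_stim)) {
    idx <- which(t_s >= onsets[i] & t_s < onsets[i] + protocol$stim_duration_s)
    covas[idx] <- stim_covas[i]
    stim_lvl[idx] <- levels_seq[i]
  }

  # two unit-variance modulations, mixed with CoVAS-dependent LF/HF weights
  fs_mod <- 4
  nm <- max(64, ceiling(duration * fs_mod))
  tm <- seq(0, nm - 1) / fs_mod
  m_lf <- with_seed(derive_seed(seed, 4),
                    spectral_modulation(nm, fs_mod, list(list(f0 = 0.10, bw = 0.02, power = 1))))
  m_hf <- with_seed(derive_seed(seed, 5),
                    spectral_modulation(nm, fs_mod, list(list(f0 = 0.25, bw = 0.03, power = 1))))
  # slow stimulus-independent wander (VLF band) of HR and ECG amplitude
  m_drift_hr <- with_seed(derive_seed(seed, 8),
                    spectral_modulation(nm, fs_mod, list(list(f0 = 0.01, bw = 0.005, power = 1))))
  m_drift_amp <- with_seed(derive_seed(seed, 9),
                    spectral_modulation(nm, fs_mod, list(list(f0 = 0.008, bw = 0.004, power = 1))))
  drift_hr_sd <- if (is.null(effect$hr_drift_sd_bpm)) 0 else effect$hr_drift_sd_bpm
  drift_amp_sd <- if (is.null(effect$amp_drift_sd_frac)) 0 else effect$amp_drift_sd_frac
  covas_at <- function(tt) {
    i <- pmin(pmax(floor(tt * fs_hz) + 1, 1), n)
    covas[i]
  }

  # beat-by-beat accumulation with momentary autonomic state
  beat_t <- numeric(0); beat_amp <- numeric(0)
  t <- 0.2
  while (t < duration - 0.4) {
    cv <- covas_at(t)
    ti <- min(max(1, round(t * fs_mod) + 1), nm)
    hr <- effect$baseline_hr_bpm + effect$hr_gain_bpm_per_pain_unit * cv +
      drift_hr_sd * m_drift_hr[ti]
    hr <- clip(hr, 35, 190)
    sdnn_s <- effect$baseline_sdnn_ms / 1000 *
      (1 - effect$sdnn_suppression_frac_at_max_pain * cv / 100)
    ratio <- max(0.05, effect$lfhf_baseline + effect$lfhf_gain * cv / 100)
    wl <- sqrt(ratio / (1 + ratio)); wh <- sqrt(1 / (1 + ratio))
    mod <- approx(tm, m_lf, xout = min(t, tm[nm]), rule = 2)$y * wl +
           approx(tm, m_hf, xout = min(t, tm[nm]), rule = 2)$y * wh
    iv <- max(0.30, 60 / hr + sdnn_s * mod)
    beat_t <- c(beat_t, t)
    beat_amp <- c(beat_amp, (1 + effect$amplitude_gain_frac_at_max_pain * cv / 100) *
                             (1 + drift_amp_sd * m_drift_amp[ti]))
    t <- t + iv
  }
  rr <- diff(c(beat_t, t))
  ecg <- synthesize_ecg(rr, fs_hz, amplitude_scale = beat_amp,
                        noise_sd_mv = ecg_noise_sd_mv, seed = derive_seed(seed, 6))
  # lead-in offset: synthesize_ecg starts at time 0, beats start at 0.2 s
  n_ecg <- length(ecg)
  pre <- round(beat_t[1] * fs_hz) - round(0.35 * rr[1] * fs_hz)
  ecg <- c(numeric(max(0, pre)), ecg)
  ecg <- if (length(ecg) >= n) ecg[seq_len(n)] else c(ecg, numeric(n - length(ecg)))
  if (ecg_noise_sd_mv > 0) {
    pad <- which(ecg == 0)
    if (length(pad))
      ecg[pad] <- with_seed(derive_seed(seed, 7), rnorm(length(pad), 0, ecg_noise_sd_mv))
  }

  structure(list(ecg = ecg, fs_hz = fs_hz, covas = covas,
                 stimulus_level = stim_lvl, t_s = t_s, seed = seed,
                 truth = effect, protocol = protocol,
                 stim_onsets_s = onsets, stim_levels = levels_seq,
                 stim_covas = stim_covas),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %.1f s at %g Hz, %d stimuli (%d painful), seed %d\n",
              length(x$ecg) / x$fs_hz, x$fs_hz, length(x$stim_onsets_s),
              sum(x$stim_covas > 0), x$seed))
  invisible(x)
}

validate_session <- function(rec) {
  lens <- c(length(rec$ecg), length(rec$covas), length(rec$stimulus_level))
  if (length(unique(lens)) != 1)
    stopf("session traces have unequal lengths: %s", paste(lens, collapse = ", "))
  if (any(rec$covas < 0 | rec$covas > 100))
    stopf("CoVAS values outside [0, 100] (first bad row: %d)",
          which(rec$covas < 0 | rec$covas > 100)[1])
  if (!is.numeric(rec$fs_hz) || rec$fs_hz <= 0) stopf("fs_hz must be positive")
  invisible(rec)
}

#' Write / read a session as CSV plus JSON sidecar
#'
#' The CSV has header `t_s,ecg_mv,covas,stimulus_level`, one row per sample;
#' sampling rate, seed and generator settings go to `<path>.json`.
#'
#' @param record a `session_record`.
#' @param path CSV file path.
#' @return `write_session_csv` returns `path` invisibly; `read_session_csv`
#'   returns a validated `session_record`.
#' @export
write_session_csv <- function(record, path) {
  validate_session(record)
  df <- data.frame(t_s = round(record$t_s, 6), ecg_mv = round(record$ecg, 6),
                   covas = round(record$covas, 6),
                   stimulus_level = record$stimulus_level)
  write.csv(df, path, row.names = FALSE)
  meta <- list(fs_hz = record$fs_hz, seed = record$seed,
               protocol = unclass(record$protocol),
               effect = unclass(record$truth))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t_s", "ecg_mv", "covas", "stimulus_level")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("session CSV %s is missing column(s): %s", path, paste(miss, collapse = ", "))
  bad <- which(df$covas < 0 | df$covas > 100)
  if (length(bad))
    stopf("session CSV %s: CoVAS outside [0, 100] at data row %d", path, bad[1])
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(readLines(side)) else NULL
  fs <- if (!is.null(meta$fs_hz)) meta$fs_hz else {
    dt <- median(diff(df$t_s))
    if (!is.finite(dt) || dt <= 0) stopf("cannot infer sampling rate from %s", path)
    1 / dt
  }
  rec <- structure(list(ecg = df$ecg_mv, fs_hz = fs, covas = df$covas,
                        stimulus_level = as.integer(df$stimulus_level),
                        t_s = df$t_s,
                        seed = if (!is.null(meta$seed)) meta$seed else NA_integer_,
                        truth = NULL, protocol = NULL,
                        stim_onsets_s = NULL),
                   class = "session_record")
  validate_session(rec)
}
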