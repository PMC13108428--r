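test_that("zero-variance tachogram is exactly metronomic", {
  rr <- generate_rr_tachogram(300, 60, 0, 1, seed = 1)
  expect_true(all(rr == 1))
  expect_equal(sum(rr), 300)
})

test_that("tachogram hits requested mean HR and SDNN at 300 s", {
  rr <- generate_rr_tachogram(300, 60, 50, 1, seed = 1)
  expect_gt(mean(rr), 0.98)
  expect_lt(mean(rr), 1.02)
  expect_lt(abs(sd(rr) * 1000 - 50) / 50, 0.10)
})

test_that("LF/HF ground truth survives a round trip through Welch analysis", {
  rr <- generate_rr_tachogram(300, 60, 50, 4, seed = 1)
  fd <- hrv_frequency_domain(rr * 1000)
  expect_gt(fd$lf_hf, 2.5)
  expect_lt(fd$lf_hf, 6.0)
})

test_that("tachogram energy stays inside the configured LF/HF bands", {
  rr <- generate_rr_tachogram(600, 60, 50, 1.5, seed = 4)
  t_beat <- cumsum(rr)
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 0.25)
  tach <- spline(t_beat, rr * 1000, xout = grid, method = "natural")$y
  ps <- welch_psd(tach - mean(tach), 4)
  inband <- band_power(ps$freq_hz, ps$psd, 0.04, 0.4)
  total <- band_power(ps$freq_hz, ps$psd, 0, 2)
  expect_gt(inband / total, 0.90)
})

test_that("tachogram generation is deterministic and rejects bad arguments", {
  expect_identical(generate_rr_tachogram(60, 70, 40, 2, seed = 5),
                   generate_rr_tachogram(60, 70, 40, 2, seed = 5))
  expect_error(generate_rr_tachogram(-1, 60, 50), "duration")
  expect_error(generate_rr_tachogram(60, 20, 50), "mean_hr_bpm")
})

test_that("synthetic ECG has the contracted length, beat count and linearity", {
  ecg <- synthesize_ecg(rep(1, 60), 250, noise_sd_mv = 0)
  expect_length(ecg, 15000)
  det <- detect_r_peaks(ecg, 250)
  expect_true(abs(length(det$r_peak_times_s) - 60) <= 1)
  e2 <- synthesize_ecg(rep(1, 60), 250, amplitude_scale = 2, noise_sd_mv = 0)
  expect_equal((max(e2) - min(e2)) / (max(ecg) - min(ecg)), 2, tolerance = 1e-12)
  expect_identical(synthesize_ecg(numeric(0), 250), numeric(0))
  expect_error(synthesize_ecg(c(1, 0.1), 250), "unphysiological")
})

test_that("session layout matches the five-level, eight-repetition protocol", {
  s <- generate_session(seed = 11)
  expect_equal(length(s$stim_onsets_s), 40)
  # CoVAS is zero whenever no stimulus is applied
  expect_true(all(s$covas[s$stimulus_level == 0] == 0))
  # the lowest (non-painful) level maps to CoVAS exactly 0
  expect_true(all(s$covas[s$stimulus_level == 1] == 0))
  # rests within the configured range
  gaps <- diff(s$stim_onsets_s) - s$protocol$stim_duration_s
  expect_true(all(gaps >= s$protocol$rest_range_s[1] - 1e-9))
  expect_true(all(gaps <= s$protocol$rest_range_s[2] + 1e-9))
})

test_that("identical protocol, effect and seed reproduce the session exactly", {
  a <- generate_session(seed = 12)
  b <- generate_session(seed = 12)
  expect_identical(a, b)
})

test_that("raising the HR gain shortens RR intervals inside pain windows", {
  lo_gain <- autonomic_effect(hr_gain_bpm_per_pain_unit = 0.05)
  hi_gain <- autonomic_effect(hr_gain_bpm_per_pain_unit = 0.40)
  prot <- tiny_protocol()
  wins <- function(effect, seed) {
    s <- generate_session(prot, effect, seed = seed, covas_targets = c(0, 80))
    ws <- suppressWarnings(segment_windows(s, session_id = "x"))
    rrs <- vapply(ws$windows, function(w) {
      if (w$covas_value > 0) {
        det <- detect_r_peaks(w$samples, w$fs_hz)
        if (!det$missing) mean(det$rr_ms) else NA_real_
      } else NA_real_
    }, 0)
    mean(rrs, na.rm = TRUE)
  }
  cmp <- vapply(1:20, function(i) wins(hi_gain, 900 + i) < wins(lo_gain, 900 + i),
                logical(1))
  expect_true(all(cmp))
})

test_that("session CSV round-trips and validates its contract", {
  s <- generate_session(tiny_protocol(), seed = 13, covas_targets = c(0, 60))
  path <- file.path(tempdir(), "sess_rt.csv")
  write_session_csv(s, path)
  s2 <- read_session_csv(path)
  expect_lt(max(abs(s$ecg - s2$ecg)), 1e-6)
  expect_lt(max(abs(s$covas - s2$covas)), 1e-6)
  expect_identical(s$stimulus_level, s2$stimulus_level)
  expect_equal(s2$fs_hz, s$fs_hz)

  # out-of-range CoVAS is rejected with the offending row named
  df <- read.csv(path)
  df$covas[5] <- 101
  bad <- file.path(tempdir(), "sess_bad.csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_session_csv(bad), "CoVAS outside")
  # missing column is a format error naming the column
  df$covas <- NULL
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_session_csv(bad), "covas")
  unlink(c(path, paste0(path, ".json"), bad))
})
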