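test_that("R-peak detection recovers synthetic beat times", {
  ecg <- synthesize_ecg(rep(1, 60), 250, noise_sd_mv = 0)
  det <- detect_r_peaks(ecg, 250)
  expect_false(det$missing)
  expect_true(abs(length(det$r_peak_times_s) - 60) <= 1)
  # beat-time accuracy within 20 ms on noiseless data
  expect_lt(max(abs(det$rr_ms - 1000)), 20)
  # constant-voltage offset leaves peak times unchanged
  det2 <- detect_r_peaks(ecg + 5, 250)
  expect_identical(det$r_peak_times_s, det2$r_peak_times_s)
  # flat line: missing flag, not zeros
  expect_true(detect_r_peaks(rep(0.3, 1000), 250)$missing)
})

test_that("basic ECG statistics match hand computations", {
  st <- ecg_statistics(c(3, -4))
  expect_equal(st$ecg_rms, sqrt(12.5), tolerance = 1e-4)
  expect_equal(st$ecg_peak_to_peak, 7)
  expect_equal(st$ecg_power, 12.5)
  cst <- ecg_statistics(rep(2.5, 10))
  expect_equal(cst$ecg_rms, 2.5)
  expect_equal(cst$ecg_peak_to_peak, 0)
  expect_true(is.na(cst$ecg_kurtosis) && is.na(cst$ecg_skewness))
  x <- rnorm(500)^3
  expect_equal(ecg_statistics(x)$ecg_skewness, -ecg_statistics(-x)$ecg_skewness)
  expect_equal(ecg_statistics(x)$ecg_kurtosis, ecg_statistics(-x)$ecg_kurtosis)
})

test_that("first-derivative RMS behaves like an analytic derivative", {
  expect_equal(derivative_statistics(rep(1, 100), 250)$decg_rms, 0)
  ramp <- (0:999) / 1000   # slope 1 mV/s at 1000 Hz
  expect_equal(derivative_statistics(ramp, 1000)$decg_rms, 1)
  fs <- 20000; f <- 3; A <- 2
  s <- A * sin(2 * pi * f * (0:(fs - 1)) / fs)
  expect_equal(derivative_statistics(s, fs)$decg_rms, A * 2 * pi * f / sqrt(2),
               tolerance = 0.01)
})

test_that("time-domain HRV matches the worked example and boundary rules", {
  td <- hrv_time_domain(c(800, 860, 870, 940))
  expect_equal(td$rr_mean, 867.5)
  expect_equal(td$rr_std, 57.37, tolerance = 1e-3)
  expect_equal(td$rr_rmssd, 53.54, tolerance = 1e-3)
  expect_equal(td$pnn50, 66.67, tolerance = 1e-3)
  eq <- hrv_time_domain(rep(900, 10))
  expect_equal(c(eq$rr_std, eq$rr_rmssd, eq$pnn50), c(0, 0, 0))
  # a 50 ms difference does not count (strictly greater than)
  expect_equal(hrv_time_domain(c(800, 850, 800))$pnn50, 0)
  expect_true(is.na(hrv_time_domain(c(800, 850))$rr_std))
})

test_that("spectral band power concentrates where the tachogram oscillates", {
  t <- seq(0, 300, by = 0.8)
  hf_tach <- 1000 + 40 * sin(2 * pi * 0.25 * t)
  fd_hf <- hrv_frequency_domain(hf_tach)
  expect_gt(fd_hf$hf_power, 20 * fd_hf$lf_power)
  lf_tach <- 1000 + 40 * sin(2 * pi * 0.10 * t)
  fd_lf <- hrv_frequency_domain(lf_tach)
  expect_gt(fd_lf$lf_hf, 10)
  flat <- hrv_frequency_domain(rep(1000, 300))
  expect_lt(flat$lf_power + flat$hf_power + flat$vlf_power, 1e-9)
})

test_that("geometric HRV follows histogram arithmetic", {
  g1 <- hrv_geometric(rep(800, 100))
  expect_equal(g1$tri_index, 1.0)
  expect_equal(g1$tinn, 1000 / 128)
  set.seed(3)
  u <- runif(1e5, 700, 900)
  g2 <- hrv_geometric(u)
  # 200 / binwidth = 25.6, minus the expected excess of the modal bin
  expect_equal(g2$tri_index, 25.6, tolerance = 0.06)
  # symmetric triangular distribution: fitted base recovered within 2 bins
  tri_sample <- 700 + (runif(2000) + runif(2000)) * 100
  g3 <- hrv_geometric(tri_sample)
  expect_lt(abs(g3$tinn - 200), 2 * 1000 / 128)
})

test_that("feature table has the contracted shape and identities", {
  tab <- strong_feature_table()
  expect_equal(nrow(tab), 240)
  expect_true(all(FEATURE_NAMES %in% names(tab)))
  expect_gte(length(FEATURE_NAMES), 18)
  expect_true(all(c("covas_value", "covas_label") %in% names(tab)))
  # algebraic identities
  expect_equal(tab$ecg_power, tab$ecg_rms^2, tolerance = 1e-12)
  ok <- !is.na(tab$hr_mean)
  expect_equal(tab$hr_mean[ok] * tab$ibi_mean[ok], rep(60000, sum(ok)),
               tolerance = 1e-9)
})

test_that("features are stable under doubling the sampling rate", {
  rr <- generate_rr_tachogram(60, 72, 45, 1.5, seed = 31)
  f250 <- synthesize_ecg(rr, 250, noise_sd_mv = 0)
  f500 <- synthesize_ecg(rr, 500, noise_sd_mv = 0)
  for (feat in c("ecg_rms", "ecg_power")) {
    a <- ecg_statistics(f250)[[feat]]
    b <- ecg_statistics(f500)[[feat]]
    expect_lt(abs(a - b) / abs(a), 0.01)
  }
  ta <- hrv_time_domain(detect_r_peaks(f250, 250)$rr_ms)
  tb <- hrv_time_domain(detect_r_peaks(f500, 500)$rr_ms)
  expect_lt(abs(ta$rr_mean - tb$rr_mean) / ta$rr_mean, 0.01)
  expect_lt(abs(ta$rr_std - tb$rr_std) / ta$rr_std, 0.05)
})

test_that("null-effect features show no corrected group difference", {
  tab <- null_feature_table()
  pain <- tab$covas_label == "pain"
  ps <- vapply(FEATURE_NAMES, function(f) {
    x <- tab[[f]][pain]; y <- tab[[f]][!pain]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(unique(c(x, y))) < 3) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, 0)
  expect_true(all(stats::p.adjust(ps, "bonferroni") > 0.05))
})
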