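# Synthetic cohort generator: beat placement, PPG alignment, artifacts,
# determinism, and record invariants.

test_that("zero-HRV profiles produce metronomic beats at the requested rate", {
  pr <- subject_profile(mean_hr = 60, hrv_sd = 0, seed = 3)
  e <- generate_ecg(pr, 10, 130)
  expect_true(abs(length(e$r_peaks) - 10) <= 1)
  expect_equal(unique(round(diff(e$r_peaks), 9)), 1.0)

  pr2 <- subject_profile(mean_hr = 120, hrv_sd = 0, seed = 4)
  e2 <- generate_ecg(pr2, 60, 130)
  hr <- 60 / mean(diff(e2$r_peaks))
  expect_equal(hr, 120, tolerance = 1e-6)
})

test_that("RR variability matches the profile SD", {
  pr <- subject_profile(mean_hr = 75, hrv_sd = 0.05, seed = 7)
  e <- generate_ecg(pr, 300, 130)
  rr_sd <- sd(diff(e$r_peaks))
  expect_lt(abs(rr_sd - 0.05) / 0.05, 0.2)
})

test_that("ECG samples and R peaks respect the record contract", {
  pr <- subject_profile(mean_hr = 70, seed = 2)
  e <- generate_ecg(pr, 20, 130)
  expect_length(e$samples, round(20 * 130))
  expect_false(is.unsorted(e$r_peaks, strictly = TRUE))
  # sampled argmax near each R peak is within half a sample of the peak time
  t <- (seq_along(e$samples) - 1) / 130
  for (rp in e$r_peaks[2:4]) {
    i <- which(t > rp - 0.1 & t < rp + 0.1)
    expect_lt(abs(t[i][which.max(e$samples[i])] - rp), 1 / 130)
  }
  expect_error(generate_ecg(pr, -1, 130))
  expect_error(generate_ecg(pr, 10, 50))
})

test_that("PPG systolic peaks sit at R peak plus lag", {
  p0 <- generate_ppg_from_ecg(1.0, 3, 64, lag = 0, notch_depth = 0)
  t <- (seq_along(p0) - 1) / 64
  expect_lt(abs(t[which.max(p0)] - 1.0), 1 / 64 + 1e-9)
  p2 <- generate_ppg_from_ecg(1.0, 3, 64, lag = 0.2, notch_depth = 0)
  expect_lt(abs(t[which.max(p2)] - 1.2), 1 / 64 + 1e-9)
  expect_error(generate_ppg_from_ecg(1.0, 3, 64, lag = -0.1))
})

test_that("cross-correlation of peak trains recovers the pulse-arrival lag", {
  pr <- subject_profile(mean_hr = 72, hrv_sd = 0.02, seed = 5)
  e <- generate_ecg(pr, 60, 130)
  ppg <- generate_ppg_from_ecg(e$r_peaks, 60, 64, lag = 0.25)
  # brute-force scan: binarized trains at 130 Hz
  fs <- 130
  n <- 60 * fs
  tr_e <- numeric(n); tr_e[round(e$r_peaks * fs) + 1] <- 1
  pk_p <- detect_ppg_peaks(ppg, 64)
  tr_p <- numeric(n); tr_p[pmin(n, round(pk_p * fs) + 1)] <- 1
  sm <- function(x) { y <- stats::filter(x, rep(1, 9), sides = 2); y[is.na(y)] <- 0; y }
  tr_e <- sm(tr_e); tr_p <- sm(tr_p)
  lags <- 0:round(0.6 * fs)
  sc <- vapply(lags, function(l)
    sum(tr_e[1:(n - l)] * tr_p[(l + 1):n]), numeric(1))
  best <- lags[which.max(sc)] / fs
  expect_lt(abs(best - 0.25), 1 / 64)
})

test_that("motion artifacts are level-scaled, seeded, and identity at zero", {
  pr <- subject_profile(mean_hr = 70, hrv_sd = 0.02, seed = 9)
  e <- generate_ecg(pr, 60, 130)
  ppg <- generate_ppg_from_ecg(e$r_peaks, 60, 64, lag = 0.25)
  expect_identical(add_motion_artifacts(ppg, 64, 0, seed = 1), ppg)
  a1 <- add_motion_artifacts(ppg, 64, 0.5, seed = 4)
  expect_identical(a1, add_motion_artifacts(ppg, 64, 0.5, seed = 4))
  expect_error(add_motion_artifacts(ppg, 64, 1.5, seed = 1))
  # stronger corruption degrades the module's own peak detector more
  truth <- e$r_peaks + 0.25
  err_at <- function(level) {
    pk <- detect_ppg_peaks(add_motion_artifacts(ppg, 64, level, seed = 8), 64)
    mean(vapply(truth[truth < 59.5], function(tt) min(abs(pk - tt)), numeric(1)))
  }
  expect_gt(err_at(0.8), err_at(0.2))
})

test_that("cohorts are deterministic with distinct subjects and valid records", {
  c1 <- make_cohort(2, 60, seed = 1)
  c2 <- make_cohort(2, 60, seed = 1)
  expect_identical(c1, c2)
  c3 <- make_cohort(34, 10, seed = 2)
  expect_length(unique(vapply(c3, `[[`, character(1), "subject_id")), 34)
  for (rec in c1) {
    expect_length(rec$ecg, round(rec$duration * rec$ecg_fs))
    expect_length(rec$ppg, round(rec$duration * rec$ppg_fs))
    expect_false(is.unsorted(rec$r_peak_times, strictly = TRUE))
  }
})

test_that("beat count is conserved between channels for artifact-free records", {
  rec <- simulate_record(subject_profile(mean_hr = 66, hrv_sd = 0.02,
                                         artifact_level = 0, seed = 31), 60)
  pk_e <- detect_r_peaks(rec$ecg, rec$ecg_fs)
  pk_p <- detect_ppg_peaks(rec$ppg, rec$ppg_fs)
  expect_lte(abs(length(pk_e) - length(pk_p)), 1)
})

test_that("cohort writer and reader round-trip the records", {
  dir <- tempfile("cohort")
  coh <- make_cohort(2, 20, seed = 3)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$ecg, coh[[1]]$ecg, tolerance = 1e-12)
  expect_equal(back[[2]]$r_peak_times, coh[[2]]$r_peak_times, tolerance = 1e-12)
  expect_identical(back[[1]]$subject_id, coh[[1]]$subject_id)
  unlink(dir, recursive = TRUE)
})
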