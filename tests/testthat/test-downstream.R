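# AF downstream harness: QRS excision, Welch band power, mixing-protocol
# bookkeeping, and the per-class baseline comparison.

test_that("QRS excision recovers the known QRS-free component", {
  pr <- subject_profile(mean_hr = 65, hrv_sd = 0.02, seed = 41)
  e <- generate_ecg(pr, 60, 130)
  t <- (seq_along(e$samples) - 1) / 130
  # the simulator's own P/T-only rendering is the ground-truth baseline
  pt_only <- ppg2ecg:::render_ecg_waves(e$r_peaks, t, pr$ecg_amplitudes,
                                        waves = c("P", "T"))
  base <- excise_qrs(e$samples, 130, widen_ms = 60, r_peaks = e$r_peaks)
  expect_length(base, length(e$samples))
  expect_lt(rmse(base, pt_only), 0.05)
})

test_that("excision spans are linear and widen_ms = 0 replaces single samples", {
  x <- c(0, 0, 10, 0, 0, 0, 8, 0, 0)
  out <- excise_qrs(x, fs = 1, widen_ms = 0, r_peaks = c(2, 6))
  expect_equal(out[3], (x[2] + x[4]) / 2)
  # interpolated span is exactly linear between its endpoints
  y <- sin(seq(0, 2, length.out = 50))
  out2 <- excise_qrs(y, fs = 10, widen_ms = 200, r_peaks = 2.5)
  drop <- (round(2.5 * 10) + 1) + (-2:2)
  keep_lo <- max(setdiff(seq_len(50), drop)[setdiff(seq_len(50), drop) < min(drop)])
  keep_hi <- min(setdiff(seq_len(50), drop)[setdiff(seq_len(50), drop) > max(drop)])
  seg <- out2[keep_lo:keep_hi]
  expect_lt(max(abs(diff(diff(seg)))), 1e-12)
  expect_error(excise_qrs(x, 1, 0, r_peaks = numeric(0)), "no R peaks")
})

test_that("no heart rate is recoverable from an excised trace", {
  pr <- subject_profile(mean_hr = 70, hrv_sd = 0, seed = 42)
  e <- generate_ecg(pr, 30, 130)
  base <- excise_qrs(e$samples, 130, widen_ms = 60, r_peaks = e$r_peaks)
  pk <- tryCatch(detect_r_peaks(base, 130), error = function(err) numeric(0))
  # QRS energy is gone: the detector finds nothing resembling the true beats
  m <- match_peaks(pk, e$r_peaks, tol = 1 / 130)
  expect_true(!length(pk) || m["recall"] < 0.2)
})

test_that("Welch band power localizes tones and satisfies Parseval on noise", {
  fs <- 130
  t <- (0:(60 * fs - 1)) / fs
  tone <- sin(2 * pi * 5 * t)
  p_total <- welch_band_power(tone, fs, c(0.05, 9))
  p_band <- welch_band_power(tone, fs, c(3, 9))
  expect_gt(p_band / p_total, 0.95)
  set.seed(8)
  wn <- rnorm(60 * fs)
  expect_equal(welch_band_power(wn, fs, c(0, fs / 2)), var(wn), tolerance = 0.1)
  expect_equal(welch_band_power(numeric(10 * fs), fs, c(0.05, 9)), 0)
  expect_error(welch_band_power(wn, fs, c(1, 100)))
})

test_that("synthetic AF records show the expected hallmarks", {
  coh <- make_af_cohort(2, 2, duration = 40, seed = 9)
  af <- coh[vapply(coh, `[[`, numeric(1), "af") == 1]
  nsr <- coh[vapply(coh, `[[`, numeric(1), "af") == 0]
  rr_sd <- function(r) sd(diff(r$r_peak_times))
  expect_gt(min(vapply(af, rr_sd, numeric(1))),
            max(vapply(nsr, rr_sd, numeric(1))))
  # fibrillatory band power is elevated in AF baselines
  bp <- function(r) {
    b <- excise_qrs(r$ecg, r$fs, 60, r$r_peak_times)
    welch_band_power(b, r$fs, c(3, 9))
  }
  expect_gt(mean(vapply(af, bp, numeric(1))),
            mean(vapply(nsr, bp, numeric(1))))
})

test_that("mixing keeps the training size constant and reports coherent metrics", {
  coh <- make_af_cohort(3, 3, duration = 24, fs = 130, seed = 10)
  segs <- ppg2ecg:::af_segments(coh, window_s = 8, fs = 130, fs_out = 16)
  sid <- vapply(segs, `[[`, character(1), "subject_id")
  test_sub <- c("AF003", "NSR003")
  train <- segs[!sid %in% test_sub]
  test <- segs[sid %in% test_sub]
  # stand-in generated segments: label-preserving noisy copies
  gen <- lapply(train, function(s) {
    s$x <- pmin(1, pmax(-1, s$x + rnorm(length(s$x), 0, 0.05))); s
  })
  res <- run_mix_experiment(train, gen, test, real_fraction = 0.75,
                            classifier = "cnnlstm", epochs = 2, hidden = 4L,
                            fc = 8L, seed = 3)
  expect_equal(res$n_train, length(train))
  cm <- attr(res, "confusion")
  expect_equal(sum(cm), length(test))
  p <- res$precision; r <- res$recall
  if (!is.na(p) && !is.na(r) && p + r > 0)
    expect_equal(res$f1, 2 * p * r / (p + r), tolerance = 1e-12)
  expect_error(run_mix_experiment(train, gen, test, real_fraction = 0.3),
               "real_fraction")
})

test_that("baseline comparison reaches its ideal values on identical pairs", {
  coh <- make_af_cohort(1, 1, duration = 40, seed = 11)
  cmp <- baseline_compare(coh, coh)
  expect_setequal(cmp$class, c("AF", "non-AF"))
  expect_true(all(cmp$rmse_mean < 1e-12))
  expect_true(all(cmp$fd_mean < 1e-12))
  expect_true(all(abs(cmp$rho_mean - 1) < 1e-9))
  expect_true(all(cmp$dpow_mean < 1e-12))
})

test_that("an injected slow drift shows up in the 0.05-1 Hz baseline band", {
  coh <- make_af_cohort(1, 1, duration = 60, seed = 12)
  drift <- lapply(coh, function(r) {
    t <- (seq_along(r$ecg) - 1) / r$fs
    r$ecg <- r$ecg + 0.1 * sin(2 * pi * 0.2 * t)
    r
  })
  cmp <- baseline_compare(coh, drift)
  expect_true(all(cmp$dpow_mean > 0))
  # the added power concentrates in the slow band
  b_r <- excise_qrs(coh[[1]]$ecg, coh[[1]]$fs, 60, coh[[1]]$r_peak_times)
  b_d <- excise_qrs(drift[[1]]$ecg, drift[[1]]$fs, 60, drift[[1]]$r_peak_times)
  slow <- welch_band_power(b_d, 130, c(0.05, 1), window_s = 20) -
    welch_band_power(b_r, 130, c(0.05, 1), window_s = 20)
  fast <- welch_band_power(b_d, 130, c(3, 9), window_s = 20) -
    welch_band_power(b_r, 130, c(3, 9), window_s = 20)
  expect_gt(slow, 10 * abs(fast))
})
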