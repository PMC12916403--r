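# Preprocessing chain: resampling, filters, median despike, segmentation,
# normalization, alignment, and pipeline bookkeeping.

test_that("cubic-spline resampling is exact on the identity grid and accurate on tones", {
  x <- sin(2 * pi * 2 * (0:639) / 64)
  expect_lt(max(abs(resample_signal(x, 64, 64) - x)), 1e-9)
  y <- resample_signal(x, 64, 130)
  expect_length(y, 1300)
  t_out <- (seq_along(y) - 1) / 130
  expect_lt(max(abs(y - sin(2 * pi * 2 * t_out))), 1e-3)
  expect_error(resample_signal(c(1, 2, 3), 64, 130), "short")
})

test_that("ECG FIR band-pass has flat passband, kills drift and DC", {
  fs <- 130
  t <- (0:(30 * fs - 1)) / fs
  tone <- sin(2 * pi * 20 * t)
  ratio <- sd(filter_ecg(tone, fs)) / sd(tone)
  expect_gt(ratio, 0.89); expect_lt(ratio, 1.12)
  t2 <- (0:(60 * fs - 1)) / fs
  drift <- sin(2 * pi * 0.05 * t2)
  expect_lt(sd(filter_ecg(drift, fs)) / sd(drift), 0.1)
  dc <- filter_ecg(rep(1, 10 * fs), fs)
  expect_lt(max(abs(dc[(2 * fs):(8 * fs)])), 1e-9)
  expect_error(filter_ecg(tone, 60))
})

test_that("PPG Butterworth band-pass passes cardiac tones and rejects drift", {
  fs <- 64
  t <- (0:(30 * fs - 1)) / fs
  tone <- sin(2 * pi * 1.2 * t)
  ratio <- sd(filter_ppg(tone, fs)) / sd(tone)
  expect_gt(ratio, 0.85); expect_lt(ratio, 1.12)
  drift <- sin(2 * pi * 0.05 * (0:(60 * fs - 1)) / fs)
  expect_lt(sd(filter_ppg(drift, fs)) / sd(drift), 0.1)
})

test_that("median despike matches the hand-enumerated running median", {
  expect_equal(median_despike(c(1, 9, 2, 8, 3), 3), c(1, 2, 8, 3, 3))
  ramp <- 1:20
  expect_equal(median_despike(ramp, 3), ramp)
  z <- numeric(50); z[25] <- 10
  expect_lt(max(abs(median_despike(z, 5))), 1e-12)
  expect_error(median_despike(1:10, 4), "odd")
})

test_that("segmentation yields the exact window count, size, and hop", {
  fs <- 130
  e <- rnorm(20 * fs); p <- rnorm(20 * fs)
  segs <- segment_pairs(e, p, fs, 4, 0.2)
  expect_length(segs, 6)                       # floor((2600 - 520)/416) + 1
  expect_true(all(vapply(segs, function(s) length(s$e), numeric(1)) == 520))
  starts <- vapply(segs, `[[`, numeric(1), "start_time") * fs
  expect_equal(unique(diff(starts)), 416)
  # zero overlap tiles the signal
  s0 <- segment_pairs(e, p, fs, 4, 0)
  expect_equal(diff(vapply(s0, `[[`, numeric(1), "start_time")), rep(4, 4))
  # brute-force enumeration of valid starts
  for (ov in c(0, 0.2, 0.5)) {
    w <- 4 * fs; hop <- round(w * (1 - ov))
    expect_length(segment_pairs(e, p, fs, 4, ov),
                  floor((length(e) - w) / hop) + 1)
  }
  expect_error(segment_pairs(rnorm(100), rnorm(100), fs, 4, 0.2), "shorter")
})

test_that("min-max normalization maps endpoints, inverts, and clips unseen extremes", {
  segs <- list(list(e = c(-2, 0, 4), p = c(0, 1, 2)))
  np <- fit_norm(segs)
  n1 <- normalize_window(segs[[1]], np)
  expect_equal(range(n1$e), c(-1, 1))
  expect_equal(range(n1$p), c(-1, 1))
  set.seed(1)
  w <- list(e = runif(50, -2, 4), p = runif(50, 0, 2))
  rt <- denormalize_window(normalize_window(w, np), np)
  expect_lt(max(abs(rt$e - w$e)), 1e-9)
  expect_lt(max(abs(rt$p - w$p)), 1e-9)
  expect_warning(out <- normalize_window(c(-3, 5), np, "e"), "clipped")
  expect_equal(out, c(-1, 1))
  expect_error(fit_norm(list(list(e = rep(1, 5), p = 1:5))), "degenerate")
})

test_that("alignment recovers the synthetic pulse-arrival lag", {
  rec0 <- simulate_record(subject_profile(mean_hr = 70, hrv_sd = 0.02,
                                          ppg_lag = 0, seed = 21), 30)
  al0 <- align_pair(rec0)
  expect_lte(al0$alignment_shift_s, 1 / 64)
  rec <- simulate_record(subject_profile(mean_hr = 70, hrv_sd = 0.02,
                                         ppg_lag = 0.3, seed = 22), 30)
  al <- align_pair(rec)
  expect_lt(abs(al$alignment_shift_s - 0.3), 1 / 130 + 1e-9)
  expect_length(al$ppg, length(rec$ppg))
  # after alignment the median signed peak offset is below one sample period
  pk_e <- detect_r_peaks(resample_signal(al$ecg, 130, 130), 130)
  pk_p <- detect_ppg_peaks(al$ppg, 64)
  offs <- vapply(pk_p, function(tp) tp - pk_e[which.min(abs(pk_e - tp))],
                 numeric(1))
  expect_lt(abs(median(offs)), 1 / 64)
})

test_that("the full chain emits valid segment pairs with shared time base", {
  pp <- fix_segments()
  expect_gt(length(pp$segments), 0)
  for (s in pp$segments) {
    expect_length(s$e, length(s$p))
    expect_length(s$e, round(s$window_s * s$fs))
    expect_true(all(abs(s$e) <= 1) && all(abs(s$p) <= 1))
    expect_true(s$subject_id %in% names(pp$norm_params))
  }
  np <- pp$norm_params[[1]]
  expect_gt(np$e_max, np$e_min)
  expect_gt(np$p_max, np$p_min)
})
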