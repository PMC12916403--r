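# Metric oracles: closed forms for RMSE / correlation, exhaustive coupling
# enumeration for the Frechet distance, brute-force MAE-HR, and peak
# detection against simulator ground truth.

test_that("RMSE matches closed forms and brute-force accumulation", {
  x <- rnorm(100)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 0.5), 0.5)
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(37); b <- rnorm(37)
    acc <- 0
    for (j in seq_along(a)) acc <- acc + (a[j] - b[j])^2
    expect_equal(rmse(a, b), sqrt(acc / 37), tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("Pearson correlation is affine-invariant and matches the textbook formula", {
  set.seed(2)
  y <- rnorm(50)
  expect_equal(pearson_r(y, 2 * y + 3), 1, tolerance = 1e-12)
  expect_equal(pearson_r(y, -y), -1, tolerance = 1e-12)
  for (i in 1:10) {
    a <- rnorm(23); b <- rnorm(23)
    oracle <- cov(a, b) / (sd(a) * sd(b)) * (22 / 23) / (22 / 23)
    expect_equal(pearson_r(a, b), oracle, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "variance")
})

test_that("discrete Frechet distance equals exhaustive coupling enumeration", {
  expect_equal(frechet_distance(c(1, 2, 1), c(1, 2, 1)), 0)
  expect_equal(frechet_distance(5, 2, tx = 1, ty = 1), 3)
  set.seed(3)
  for (i in 1:200) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    A <- cbind(seq_len(n), rnorm(n))
    B <- cbind(seq_len(m), rnorm(m))
    expect_equal(frechet_distance(A[, 2], B[, 2], A[, 1], B[, 1]),
                 frechet_bruteforce(A, B), tolerance = 1e-12)
  }
})

test_that("Frechet distance is symmetric, non-negative, and zero iff identical", {
  set.seed(4)
  for (i in 1:25) {
    a <- rnorm(8); b <- rnorm(8)
    d1 <- frechet_distance(a, b)
    expect_equal(d1, frechet_distance(b, a), tolerance = 1e-12)
    expect_gte(d1, 0)
  }
  a <- rnorm(10)
  expect_identical(frechet_distance(a, a), 0)
  expect_gt(frechet_distance(a, a + 1e-6), 0)
  expect_error(frechet_distance(numeric(0), 1), "empty")
})

test_that("MAE-HR matches brute-force per-segment recomputation and handles exclusions", {
  gt <- list(c(0, 1, 2, 3), c(0, 0.5, 1.0, 1.5))
  expect_equal(mae_hr(gt, gt)$mae, 0)
  q <- list(c(0, 0.5, 1), c(0, 0.5, 1.0))
  r <- mae_hr(list(c(0, 1, 2)), list(c(0, 0.5, 1)))
  expect_equal(r$mae, 60)
  set.seed(5)
  gt2 <- lapply(1:8, function(i) cumsum(runif(sample(3:7, 1), 0.5, 1.2)))
  q2 <- lapply(1:8, function(i) cumsum(runif(sample(3:7, 1), 0.5, 1.2)))
  res <- mae_hr(gt2, q2)
  manual <- mean(vapply(1:8, function(i)
    abs(60 / mean(diff(gt2[[i]])) - 60 / mean(diff(q2[[i]]))), numeric(1)))
  expect_equal(res$mae, manual, tolerance = 1e-12)
  # a segment with < 2 peaks is excluded and counted
  res2 <- mae_hr(c(gt2, list(1.0)), c(q2, list(c(1, 2))))
  expect_equal(res2$n, 8)
  expect_equal(res2$excluded, 1)
  expect_error(mae_hr(list(1), list(c(1, 2))), "zero retained")
})

test_that("R-peak detection is exact on clean synthetic ECG, including negated traces", {
  ee <- generate_ecg(subject_profile(mean_hr = 60, hrv_sd = 0, seed = 2), 30, 130)
  pk <- detect_r_peaks(ee$samples, 130)
  expect_lte(abs(length(pk) - 30), 1)
  m <- match_peaks(pk, ee$r_peaks, tol = 1 / 130 + 1e-9)
  expect_equal(unname(m), c(1, 1))
  pk_neg <- detect_r_peaks(-ee$samples, 130)
  m2 <- match_peaks(pk_neg, ee$r_peaks, tol = 1 / 130 + 1e-9)
  expect_equal(unname(m2), c(1, 1))
  expect_gte(min(diff(pk)), 0.2)
  expect_error(detect_r_peaks(rep(0, 10 * 130), 130), "flat")
})

test_that("systolic-peak detection recovers clean PPG beats within tolerance", {
  ee <- generate_ecg(subject_profile(mean_hr = 75, hrv_sd = 0.02, seed = 6), 60, 130)
  ppg <- generate_ppg_from_ecg(ee$r_peaks, 60, 64, lag = 0.25)
  pk <- detect_ppg_peaks(ppg, 64)
  truth <- ee$r_peaks + 0.25
  truth <- truth[truth < 60 - 0.4]
  expect_lte(abs(length(pk) - length(truth)), 1)
  m <- match_peaks(pk, truth, tol = 2 / 64 + 1e-9)
  expect_gte(m["recall"], 1 - 1 / length(truth))
  expect_gte(m["precision"], 1 - 1 / length(pk))
  expect_gte(min(diff(pk)), 0.25)
  # heavy artifacts strictly degrade detection
  noisy <- add_motion_artifacts(ppg, 64, 0.8, seed = 3)
  m_noisy <- match_peaks(detect_ppg_peaks(noisy, 64), truth, tol = 2 / 64)
  expect_lt(m_noisy["recall"] * m_noisy["precision"],
            m["recall"] * m["precision"])
})

test_that("the identity-on-ECG oracle achieves the perfect-generator limit", {
  pp <- fix_segments()
  segs <- pp$segments[1:6]
  per <- evaluate_segments(segs, function(p, seg) seg$e, pp$norm_params, 32)
  expect_true(all(per$rmse < 1e-12))
  expect_true(all(per$fd < 1e-12))
  expect_true(all(abs(per$rho - 1) < 1e-9))
  mh <- mae_hr(attr(per, "peaks_gt"), attr(per, "peaks_gen"))
  expect_equal(mh$mae, 0)
})

test_that("a degenerate zero generator is flagged, not silently dropped", {
  pp <- fix_segments()
  segs <- pp$segments[1:3]
  per <- evaluate_segments(segs, function(p) p * 0, pp$norm_params, 32)
  expect_true(all(per$degenerate | !is.na(per$rho)))
  expect_equal(nrow(per), 3)
  expect_true(any(is.na(per$rho)))
})

test_that("the PPG heart-rate column is independent of the generator", {
  pp <- fix_segments()
  segs <- pp$segments[1:4]
  p1 <- evaluate_segments(segs, function(p, seg) seg$e, pp$norm_params, 32)
  p2 <- evaluate_segments(segs, function(p) p * 0, pp$norm_params, 32)
  expect_identical(attr(p1, "peaks_ppg"), attr(p2, "peaks_ppg"))
})
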