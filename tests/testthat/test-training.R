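# Loss identities, the analytic gradient-penalty oracle, LOSO bookkeeping,
# and grid/config validation.

test_that("generator and critic losses match independent arithmetic", {
  expect_equal(generator_loss(c(1, 1, 1)), -1)
  expect_equal(generator_loss(0), 0)
  expect_equal(critic_loss(c(2, 2), c(1, 1), 0), -1)
  expect_equal(critic_loss(c(3, -1), c(3, -1), 0), 0)
  set.seed(1)
  for (i in 1:20) {
    r <- rnorm(7); f <- rnorm(5); g <- abs(rnorm(1))
    acc_r <- 0; for (v in r) acc_r <- acc_r + v
    acc_f <- 0; for (v in f) acc_f <- acc_f + v
    expect_equal(generator_loss(f), -acc_f / 5, tolerance = 1e-9)
    expect_equal(critic_loss(r, f, g), -acc_r / 7 + acc_f / 5 + g,
                 tolerance = 1e-9)
  }
})

test_that("gradient penalty equals lambda (|c| - 1)^2 for linear critics", {
  set.seed(2)
  B <- 4L; L <- 6L
  for (cc in c(0.5, 1, 2)) {
    lin <- function(x, B2, L2) {
      S <- matrix(0, B2, B2 * L2)
      for (b in seq_len(B2)) S[b, (b - 1L) * L2 + 1L] <- cc
      ad_matmul(ad_const(S), x)
    }
    for (lam in c(0, 6, 30)) {
      r <- gradient_penalty(lin, matrix(rnorm(B * L), B, L),
                            matrix(rnorm(B * L), B, L), lambda = lam, seed = 3)
      expect_equal(r$value, lam * (abs(cc) - 1)^2, tolerance = 1e-9)
      expect_equal(unname(r$grad_norms), rep(abs(cc), B), tolerance = 1e-9)
    }
  }
})

test_that("gradient penalty differentiates through the critic parameters", {
  # critic(x) = w * x[1]; d(penalty)/dw = 2 lambda (w - 1) for w > 0
  w <- ad_param(matrix(1.5, 1, 1))
  B <- 2L; L <- 3L
  lin <- function(x, B2, L2) {
    S <- matrix(0, B2, B2 * L2)
    for (b in seq_len(B2)) S[b, (b - 1L) * L2 + 1L] <- 1
    ad_matmul(ad_matmul(ad_const(S), x), w)
  }
  r <- gradient_penalty(lin, matrix(rnorm(6), B, L), matrix(rnorm(6), B, L),
                        lambda = 30, seed = 1)
  ppg2ecg:::zero_grads(list(w))
  ppg2ecg:::ad_backward(r$penalty, list(w))
  expect_equal(w$g[1, 1], 2 * 30 * (1.5 - 1), tolerance = 1e-6)
})

test_that("LOSO folds partition subjects with leakage-free validation splits", {
  ids <- sprintf("S%02d", 1:34)
  folds <- loso_folds(ids, val_fraction = 0.1, seed = 3)
  expect_length(folds, 34)
  expect_setequal(vapply(folds, `[[`, character(1), "test_subject"), ids)
  for (f in folds[c(1, 17, 34)]) {
    expect_false(f$test_subject %in% f$train_subjects)
    expect_setequal(c(f$test_subject, f$train_subjects), ids)
  }
  expect_error(loso_folds(c("a", "a", "b")), "duplicate")

  pp <- fix_segments()
  sids <- unique(vapply(pp$segments, `[[`, character(1), "subject_id"))
  f2 <- loso_folds(sids, val_fraction = 0.2, seed = 5)
  for (fold in f2) {
    sp <- split_segments(pp$segments, fold)
    seg_sid <- vapply(pp$segments, `[[`, character(1), "subject_id")
    expect_false(any(seg_sid[sp$train] == fold$test_subject))
    expect_false(any(seg_sid[sp$val] == fold$test_subject))
    expect_true(all(seg_sid[sp$test] == fold$test_subject))
    expect_length(intersect(sp$train, sp$val), 0)
    npool <- sum(seg_sid != fold$test_subject)
    expect_lte(abs(length(sp$val) - round(0.2 * npool)), 1)
  }
})

test_that("the grid expander honors the search lists and rejects bad decay rates", {
  g <- expand_grid_config()
  expect_true(all(g$beta1 %in% c(0.5, 0.9)))
  expect_true(all(g$beta2 %in% c(0.5, 0.9)))
  expect_true(all(g$lambda %in% c(4, 6, 30, 50)))
  expect_true(all(g$batch %in% c(64, 128)))
  g2 <- expand_grid_config(budget = 10, seed = 1)
  expect_equal(nrow(g2), 10)
  expect_error(train_config(beta1 = 3, beta2 = 1))
  expect_error(train_config(beta1 = 0.9, beta2 = 1))
})

test_that("pretext pre-training is deterministic and learns above chance", {
  pp <- fix_segments()
  segs <- lapply(pp$segments[1:8], `[[`, "e")
  px <- build_pretext_dataset(segs, seed = 21)
  r1 <- pretrain_multitask(px, small_disc_cfg(), epochs = 2, batch = 16,
                           folds = 0, seed = 2)
  r2 <- pretrain_multitask(px, small_disc_cfg(), epochs = 2, batch = 16,
                           folds = 0, seed = 2)
  expect_identical(r1$history, r2$history)
  expect_lt(tail(r1$history, 1), r1$history[1])
  # single-class task is rejected
  px_bad <- px
  px_bad$labels[, "negate"] <- 0L
  expect_error(pretrain_multitask(px_bad, small_disc_cfg(), epochs = 1,
                                  folds = 0), "single class")
})
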