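# Model contracts: shape preservation, output ranges, determinism, freezing,
# and end-to-end differentiability.

test_that("generator preserves length and stays inside (-1, 1)", {
  gen <- generator_init(small_gen_cfg(), seed = 1)
  for (L in c(128, 130, 520)) {          # multiple, non-multiple, native 4 s
    x <- matrix(runif(2 * L, -1, 1), 2, L)
    y <- generator_forward(x, gen)
    expect_equal(dim(y), c(2, L))
    expect_lte(max(abs(y)), 1)        # Tanh head; saturation rounds to 1.0
  }
  expect_error(generator_forward(numeric(0), gen), "empty")
})

test_that("default-size generator maps a 520-sample window to 520 samples", {
  gen <- generator_init(generator_config(), seed = 2)
  y <- generator_forward(runif(520, -1, 1), gen)
  expect_length(y, 520)
  expect_lte(max(abs(y)), 1)
})

test_that("generator inference is deterministic with dropout off", {
  gen <- generator_init(small_gen_cfg(), seed = 3)
  x <- matrix(runif(128, -1, 1), 1)
  expect_identical(generator_forward(x, gen), generator_forward(x, gen))
})

test_that("critic emits unbounded scalar scores, six pretext logits, and the embedding", {
  disc <- discriminator_init(small_disc_cfg(), seed = 4)
  x <- matrix(runif(3 * 128, -1, 1), 3, 128)
  cr <- discriminator_forward(x, disc, mode = "critic")
  expect_equal(dim(cr$out$v), c(3, 1))
  px <- discriminator_forward(x, disc, mode = "pretext")
  expect_equal(dim(px$out$v), c(3, 6))
  # default configuration: penultimate-FC embedding is 512-wide
  dfull <- discriminator_init(discriminator_config(), seed = 5)
  fw <- discriminator_forward(matrix(runif(520, -1, 1), 1), dfull, mode = "critic")
  expect_equal(ncol(fw$embedding$v), 512)
})

test_that("one optimization step through the bottleneck reduces reconstruction loss", {
  gen <- generator_init(small_gen_cfg(), seed = 6)
  p <- matrix(runif(128, -1, 1), 1)
  e <- matrix(sin(2 * pi * (1:128) / 32) * 0.5, 1)
  loss_of <- function() {
    fk <- generator_forward(ad_const(ppg2ecg:::batch_to_node_rows(p)), gen,
                            B = 1L, L = 128L)
    d <- ppg2ecg:::ad_sub(fk, ad_const(ppg2ecg:::batch_to_node_rows(e)))
    ad_mean(ad_mul(d, d))
  }
  l0 <- loss_of()
  opt <- ppg2ecg:::adam_init(gen$params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999)
  ppg2ecg:::zero_grads(gen$params)
  ppg2ecg:::ad_backward(l0, gen$params)
  opt <- ppg2ecg:::adam_step(opt)
  expect_lt(loss_of()$v[1], l0$v[1])
})

test_that("frozen Transformer tensors stay bit-identical while heads move", {
  pp <- fix_segments()
  segs <- pp$segments[1:6]
  disc <- discriminator_init(small_disc_cfg(), seed = 7)
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(disc, ck, seed = 7)
  gen <- generator_init(small_gen_cfg(), seed = 8)
  disc2 <- discriminator_init(small_disc_cfg(), seed = 9)
  before_tr <- lapply(disc2$transformer_params, function(p) p$v)   # overwritten on load
  fit <- train_gan(segs, gen, disc2,
                   train_config(epochs = 1, batch = 6, critic_steps = 1,
                                lr = 0.001, seed = 1),
                   gp = gp_params(6), pretrained = ck, steps_per_epoch = 1)
  loaded <- readRDS(ck)
  after_tr <- lapply(fit$disc$transformer_params, function(p) p$v)
  src <- discriminator_init(small_disc_cfg(), seed = 7)
  src <- load_checkpoint(src, ck)
  expect_identical(after_tr, lapply(src$transformer_params, function(p) p$v))
  # critic head did move
  head_moved <- !identical(lapply(fit$disc$critic_head_params, function(p) p$v),
                           lapply(src$critic_head_params, function(p) p$v))
  expect_true(head_moved)
})

test_that("AF classifiers output probabilities with the right pooling arithmetic", {
  m <- bidlstm_init(hidden = 4L, fc = 8L, seed = 1)
  x <- matrix(runif(2 * 40, -1, 1), 2, 40)
  pr <- classifier_forward(x, m)$prob$v
  expect_equal(dim(pr), c(2, 1))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(classifier_forward(x, m)$prob$v, pr)
  # reversing input keeps the output shape
  expect_equal(dim(classifier_forward(x[, 40:1], m)$prob$v), c(2, 1))
  m2 <- cnnlstm_init(hidden = 4L, fc = 8L, filters = 3L, seed = 2)
  pr2 <- classifier_forward(x, m2)$prob$v
  expect_true(all(pr2 >= 0 & pr2 <= 1))
  # temporal length after conv (kernel 4, same-ish padding) and two pools
  TT <- 40
  T1 <- m2$conv1$len_out(TT) %/% 2L
  T2 <- m2$conv2$len_out(T1) %/% 2L
  expect_equal(T2, floor(floor((TT - 1) / 2) - 1) %/% 2)
  # the hybrid model carries convolutional parameters the Bid-LSTM lacks
  expect_gt(ppg2ecg:::n_params(c(m2$conv1$params, m2$conv2$params)), 0)
})

test_that("checkpoints round-trip parameters with a JSON header", {
  gen <- generator_init(small_gen_cfg(), seed = 10)
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(gen, ck, seed = 10, epoch = 5)
  gen2 <- generator_init(small_gen_cfg(), seed = 11)
  gen2 <- load_checkpoint(gen2, ck)
  expect_identical(lapply(gen2$params, function(p) p$v),
                   lapply(gen$params, function(p) p$v))
  expect_equal(gen2$ckpt_header$epoch, 5)
  counts <- inspect_model(gen)
  expect_gt(counts[["total"]], 0)
  expect_equal(counts[["total"]],
               counts[["encoder"]] + counts[["bottleneck"]] + counts[["decoder"]])
})
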