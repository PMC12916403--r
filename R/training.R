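# Training: Wasserstein losses with gradient penalty, multi-task pretext
# pre-training, frozen-transfer adversarial fine-tuning, LOSO folds and the
# hyperparameter grid.

as_batch <- function(x) if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)

#' Wasserstein generator loss: negative mean critic score on generated samples
#' @param critic_scores_on_fake numeric vector of critic scores
#' @return scalar loss
#' @export
generator_loss <- function(critic_scores_on_fake) {
  stopifnot(length(critic_scores_on_fake) > 0)
  -mean(critic_scores_on_fake)
}

#' Wasserstein critic loss with gradient penalty term
#' @param scores_real,scores_fake numeric critic scores on real / generated batches
#' @param gp scalar gradient-penalty value
#' @return scalar loss \code{-mean(real) + mean(fake) + gp}
#' @export
critic_loss <- function(scores_real, scores_fake, gp = 0) {
  stopifnot(length(scores_real) > 0, length(scores_fake) > 0)
  -mean(scores_real) + mean(scores_fake) + gp
}

#' Gradient-penalty parameters
#' @param lambda penalty coefficient (>= 0)
#' @export
gp_params <- function(lambda = 6) {
  stopifnot(lambda >= 0)
  list(lambda = lambda)
}

# indicator matrix summing the B*L input rows of each sample
sample_rowsum_matrix <- function(B, L) {
  S <- matrix(0, B, B * L)
  for (b in seq_len(B)) S[b, ((b - 1L) * L + 1L):(b * L)] <- 1
  S
}

#' Gradient penalty at interpolated samples
#'
#' Per sample draws epsilon ~ U(0, 1), forms
#' \code{xhat = eps * real + (1 - eps) * fake}, differentiates the critic
#' score with respect to \code{xhat}, and returns
#' \code{lambda * mean((||grad||_2 - 1)^2)}. The returned \code{penalty} node
#' is differentiable with respect to the critic parameters (double backprop).
#'
#' @param critic_fn function (node, B, L) -> scores node (B x 1)
#' @param real,fake numeric B x L batches (same shape)
#' @param lambda penalty coefficient
#' @param seed integer seed for the epsilon draws
#' @return list: \code{value} (numeric), \code{penalty} (node),
#'   \code{grad_norms} (numeric, per sample)
#' @export
gradient_penalty <- function(critic_fn, real, fake, lambda, seed = 1L) {
  real <- as_batch(real); fake <- as_batch(fake)
  stopifnot(all(dim(real) == dim(fake)))
  B <- nrow(real); L <- ncol(real)
  eps <- with_seed(seed, stats::runif(B))
  xh <- real * eps + fake * (1 - eps)
  xnode <- ad_param(batch_to_node_rows(xh), "xhat")
  scores <- critic_fn(xnode, B, L)
  gx <- ad_grad(ad_sum(scores), list(xnode))[[1L]]
  S <- ad_const(sample_rowsum_matrix(B, L))
  n2 <- ad_matmul(S, ad_mul(gx, gx))
  nrm <- ad_sqrt(ad_sadd(n2, 1e-12))
  dev <- ad_sadd(nrm, -1)
  pen <- ad_smul(ad_mean(ad_mul(dev, dev)), lambda)
  list(value = pen$v[1L], penalty = pen, grad_norms = sqrt(n2$v[, 1L]))
}

#' Training configuration
#'
#' @param epochs training epochs
#' @param batch batch size
#' @param lr Adam learning rate
#' @param beta1,beta2 Adam exponential decay rates (must lie in (0, 1))
#' @param critic_steps critic updates per generator update
#' @param patience early-stopping patience (epochs) on validation RMSE
#' @param divergence_bound abort threshold on |critic loss|
#' @param seed integer seed
#' @export
train_config <- function(epochs = 90L, batch = 128L, lr = 1e-3, beta1 = 0.5,
                         beta2 = 0.9, critic_steps = 5L, patience = 10L,
                         divergence_bound = 1e6, seed = 1L) {
  stopifnot(epochs >= 1, batch >= 1, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  list(epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
       beta1 = beta1, beta2 = beta2, critic_steps = as.integer(critic_steps),
       patience = as.integer(patience), divergence_bound = divergence_bound,
       seed = as.integer(seed))
}

segments_to_matrices <- function(segments) {
  P <- do.call(rbind, lapply(segments, `[[`, "p"))
  E <- do.call(rbind, lapply(segments, `[[`, "e"))
  list(P = P, E = E)
}

#' Overfit a generator on a handful of segment pairs by reconstruction
#'
#' Plain mean-squared-error training; a capacity check that the architecture
#' can represent the PPG-to-ECG map at all.
#'
#' @param segments list of normalized segment pairs
#' @param gen generator model
#' @param steps optimization steps
#' @param lr Adam learning rate
#' @param seed integer seed
#' @return list with final normalized-scale \code{rmse} and the \code{history}
#' @export
train_generator_overfit <- function(segments, gen, steps = 500L, lr = 2e-3,
                                    seed = 1L) {
  m <- segments_to_matrices(segments)
  B <- nrow(m$P); L <- ncol(m$P)
  eN <- ad_const(batch_to_node_rows(m$E))
  opt <- adam_init(gen$params, lr = lr, beta1 = 0.9, beta2 = 0.999)
  hist <- numeric(0)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      pn <- ad_const(batch_to_node_rows(m$P))
      fake <- generator_forward(pn, gen, train = FALSE, B = B, L = L)
      diff <- ad_sub(fake, eN)
      loss <- ad_mean(ad_mul(diff, diff))
      zero_grads(gen$params)
      ad_backward(loss, gen$params)
      opt <- adam_step(opt)
      if (s %% 25L == 0L || s == steps) hist <- c(hist, sqrt(loss$v[1L]))
    }
  })
  list(rmse = utils::tail(hist, 1L), history = hist)
}

#' Adversarial WGAN-GP training with optional frozen pretext transfer
#'
#' Alternates \code{critic_steps} critic updates (Wasserstein loss plus
#' gradient penalty) with one generator update. When \code{pretrained} is a
#' critic checkpoint path, its weights are loaded and the Transformer blocks
#' (CLS, positions, attention and MLP tensors) are frozen; only the conv
#' encoder and the FC critic head continue to train. Early stopping monitors
#' a validation reconstruction RMSE; training aborts if the critic loss
#' exceeds \code{divergence_bound} for 3 consecutive epochs.
#'
#' @param segments training segment pairs (normalized)
#' @param gen,disc initialized models
#' @param cfg a \code{\link{train_config}}
#' @param gp a \code{\link{gp_params}}
#' @param pretrained optional path to a pretext critic checkpoint
#' @param val_segments optional validation pairs for early stopping
#' @param steps_per_epoch generator updates per epoch (default: one pass)
#' @return list: \code{gen}, \code{disc}, \code{history} data.frame with
#'   columns epoch, l_g, l_d, gp, grad_norm_mean, val_rmse
#' @export
train_gan <- function(segments, gen, disc, cfg = train_config(),
                      gp = gp_params(), pretrained = NULL,
                      val_segments = NULL, steps_per_epoch = NULL) {
  stopifnot(length(segments) >= 1)
  m <- segments_to_matrices(segments)
  n <- nrow(m$P); L <- ncol(m$P)
  if (!is.null(pretrained)) disc <- load_checkpoint(disc, pretrained)
  frozen <- if (!is.null(pretrained)) disc$transformer_params else list()
  frozen_ids <- vapply(frozen, function(p) p$gid, numeric(1))
  d_train <- Filter(function(p) !(p$gid %in% frozen_ids), disc$params)
  opt_d <- adam_init(d_train, lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2)
  opt_g <- adam_init(gen$params, lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2)
  if (is.null(steps_per_epoch)) steps_per_epoch <- max(1L, n %/% cfg$batch)
  critic_fn <- function(x, B, L2)
    discriminator_forward(x, disc, mode = "critic", B = B, L = L2)$out
  hist <- list()
  best_val <- Inf; wait <- 0L; blown <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lg <- ld <- gpv <- gn <- numeric(0)
      for (st in seq_len(steps_per_epoch)) {
        for (cs in seq_len(cfg$critic_steps)) {
          idx <- sample.int(n, min(cfg$batch, n))
          Pb <- m$P[idx, , drop = FALSE]; Eb <- m$E[idx, , drop = FALSE]
          fake <- as_batch(generator_forward(Pb, gen))
          sr <- discriminator_forward(Eb, disc, mode = "critic")$out
          sf <- discriminator_forward(fake, disc, mode = "critic")$out
          gpr <- gradient_penalty(critic_fn, Eb, fake, gp$lambda,
                                  seed = sample.int(.Machine$integer.max, 1))
          loss_d <- ad_add(ad_sub(ad_mean(sf), ad_mean(sr)), gpr$penalty)
          zero_grads(d_train)
          ad_backward(loss_d, d_train)
          opt_d <- adam_step(opt_d)
          ld <- c(ld, loss_d$v[1L]); gpv <- c(gpv, gpr$value)
          gn <- c(gn, mean(gpr$grad_norms))
        }
        idx <- sample.int(n, min(cfg$batch, n))
        Pb <- m$P[idx, , drop = FALSE]
        B <- nrow(Pb)
        pn <- ad_const(batch_to_node_rows(Pb))
        fk <- generator_forward(pn, gen, B = B, L = L)
        sc <- discriminator_forward(fk, disc, mode = "critic", B = B, L = L)$out
        loss_g <- ad_neg(ad_mean(sc))
        zero_grads(gen$params)
        ad_backward(loss_g, gen$params)
        opt_g <- adam_step(opt_g)
        lg <- c(lg, loss_g$v[1L])
      }
      vseg <- if (is.null(val_segments)) segments else val_segments
      vm <- segments_to_matrices(vseg)
      vf <- as_batch(generator_forward(vm$P, gen))
      val_rmse <- sqrt(mean((vf - vm$E)^2))
      hist[[ep]] <- data.frame(epoch = ep, l_g = mean(lg), l_d = mean(ld),
                               gp = mean(gpv), grad_norm_mean = mean(gn),
                               val_rmse = val_rmse)
      blown <- if (abs(mean(ld)) > cfg$divergence_bound) blown + 1L else 0L
      if (blown >= 3L) {
        warning("critic loss diverged for 3 consecutive epochs; aborting")
        break
      }
      if (val_rmse < best_val - 1e-6) {
        best_val <- val_rmse; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  list(gen = gen, disc = disc, history = do.call(rbind, hist))
}

#' Multi-task self-supervised pretext pre-training of the critic
#'
#' Trains the critic trunk plus the 128/128 task trunk on the six binary
#' transformation-recognition tasks (equal weights, logistic losses), with
#' k-fold cross-validated per-task accuracy.
#'
#' @param pretext dataset from \code{\link{build_pretext_dataset}}
#' @param disc_cfg a \code{\link{discriminator_config}}
#' @param epochs,batch,lr optimization settings
#' @param folds cross-validation folds (paper protocol: 10)
#' @param seed integer seed
#' @return list: \code{model} (critic trained on all data), \code{cv_accuracy}
#'   (folds x 6 matrix), \code{history} (per-epoch mean loss)
#' @export
pretrain_multitask <- function(pretext, disc_cfg = discriminator_config(),
                               epochs = 10L, batch = 32L, lr = 1e-3,
                               folds = 10L, seed = 1L) {
  x <- pretext$x; y <- pretext$labels
  for (k in seq_len(ncol(y)))
    if (length(unique(y[, k])) < 2) stop("task ", colnames(y)[k], " has a single class")
  n <- nrow(x)
  train_one <- function(xi, yi, sd0) {
    disc <- discriminator_init(disc_cfg, seed = sd0)
    params <- c(disc$encoder_params, disc$transformer_params,
                disc$pretext_head_params)
    opt <- adam_init(params, lr = lr, beta1 = 0.9, beta2 = 0.999)
    losses <- numeric(0)
    with_seed(sd0 + 1L, {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(nrow(xi))
        epl <- numeric(0)
        for (b0 in seq(1L, nrow(xi), by = batch)) {
          idx <- ord[b0:min(b0 + batch - 1L, nrow(xi))]
          fw <- discriminator_forward(xi[idx, , drop = FALSE], disc,
                                      mode = "pretext")
          z <- fw$out
          bce <- ad_mean(ad_sub(ad_softplus(z),
                                ad_mul(z, ad_const(yi[idx, , drop = FALSE]))))
          zero_grads(params)
          ad_backward(bce, params)
          opt <- adam_step(opt)
          epl <- c(epl, bce$v[1L])
        }
        losses <- c(losses, mean(epl))
      }
    })
    list(disc = disc, losses = losses)
  }
  acc <- NULL
  if (folds >= 2L) {
    fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
    acc <- matrix(NA_real_, folds, ncol(y), dimnames = list(NULL, colnames(y)))
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      fit <- train_one(x[tr, , drop = FALSE], y[tr, , drop = FALSE], seed + f)
      zz <- discriminator_forward(x[!tr, , drop = FALSE], fit$disc,
                                  mode = "pretext")$out$v
      pred <- (zz > 0) * 1L
      acc[f, ] <- colMeans(pred == y[!tr, , drop = FALSE])
    }
  }
  full <- train_one(x, y, seed)
  list(model = full$disc, cv_accuracy = acc, history = full$losses)
}

#' Leave-one-subject-out folds
#'
#' @param subject_ids character vector of unique ids
#' @param val_fraction fraction of training segments used for validation
#' @param seed integer seed
#' @return list of folds: fold_id, test_subject, train_subjects, val_fraction
#' @export
loso_folds <- function(subject_ids, val_fraction = 0.1, seed = 1L) {
  stopifnot(length(subject_ids) >= 2)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  lapply(seq_along(subject_ids), function(i)
    list(fold_id = i, test_subject = subject_ids[i],
         train_subjects = subject_ids[-i], val_fraction = val_fraction,
         seed = seed))
}

#' Split pooled segments according to a LOSO fold
#'
#' Validation segments are drawn only from training subjects.
#'
#' @param segments pooled segment list (each carrying \code{subject_id})
#' @param fold one fold from \code{\link{loso_folds}}
#' @return list of index vectors: train, val, test
#' @export
split_segments <- function(segments, fold) {
  sid <- vapply(segments, `[[`, character(1), "subject_id")
  test <- which(sid == fold$test_subject)
  pool <- which(sid %in% fold$train_subjects)
  nval <- round(fold$val_fraction * length(pool))
  val <- with_seed(fold$seed + fold$fold_id,
                   sort(sample(pool, nval)))
  train <- setdiff(pool, val)
  list(train = train, val = val, test = test)
}

#' Expand the hyperparameter grid
#'
#' Builds the full factorial over the search lists (Adam decay pairs,
#' gradient-penalty coefficient, FC width, learning rate, dropout, batch
#' size), drops decay values not in (0, 1) -- the listed values 1 and 3 are
#' not admissible exponential decay rates -- and optionally samples a
#' \code{budget}-sized subset.
#'
#' @param budget maximum number of configurations returned (NULL = all)
#' @param seed integer seed for subsampling
#' @return data.frame of configurations
#' @export
expand_grid_config <- function(budget = NULL, seed = 1L) {
  betas <- c(0.5, 0.9, 1, 3)
  ok <- betas[betas > 0 & betas < 1]
  g <- expand.grid(beta1 = ok, beta2 = ok,
                   lambda = c(4, 6, 30, 50),
                   fc = c(128, 256, 512),
                   lr = c(0.001, 0.002, 0.005),
                   dropout = c(0.2, 0.4, 0.5, 0.7),
                   batch = c(64, 128))
  if (!is.null(budget) && budget < nrow(g))
    g <- g[with_seed(seed, sort(sample.int(nrow(g), budget))), ]
  rownames(g) <- NULL
  g
}
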