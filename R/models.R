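# Model definitions: 1-D UNet generator with a Transformer bottleneck,
# Transformer critic with CLS token, and the two AF classifiers.

# gather a set of rows of a node (linear op, built on ad_gather)
rows_gather <- function(x, rowidx) {
  nr <- nrow(x$v); nc <- ncol(x$v)
  idx <- outer(as.integer(rowidx), (seq_len(nc) - 1L) * nr, "+")
  storage.mode(idx) <- "integer"
  ad_gather(x, idx)
}

# block-average pooling matrix mapping B*L rows to B*s rows
pool_matrix <- function(B, L, s) {
  P <- matrix(0, B * s, B * L)
  bounds <- split_bounds(L, s)
  for (b in seq_len(B)) {
    for (i in seq_len(s)) {
      cols <- ((b - 1L) * L + bounds[i, 1]):((b - 1L) * L + bounds[i, 2])
      P[(b - 1L) * s + i, cols] <- 1 / length(cols)
    }
  }
  P
}

# ---- generator --------------------------------------------------------------

#' Generator architecture configuration
#'
#' A UNet-style 1-D convolutional encoder/decoder (depth \code{L}, stride-2
#' downsampling) around a Transformer bottleneck with causal self-attention.
#' The encoder channel schedule ends at 8 channels which the bottleneck
#' expands to 16 before tokenization.
#'
#' @param L encoder/decoder depth (default 4)
#' @param enc_channels per-layer encoder channel counts (last entry 8 by default)
#' @param kernel convolution kernel size (odd)
#' @param d_model bottleneck token width
#' @param n_layers,heads Transformer depth and attention heads
#' @param ffn feed-forward width (default 2 * d_model)
#' @param dropout dropout fraction inside Transformer MLPs
#' @param max_tokens largest token count supported (positional table size)
#' @return a \code{generator_config}
#' @export
generator_config <- function(L = 4L, enc_channels = c(16L, 16L, 8L, 8L),
                             kernel = 15L, d_model = 64L, n_layers = 2L,
                             heads = 2L, ffn = 2L * d_model, dropout = 0.2,
                             max_tokens = 1300L) {
  stopifnot(L >= 1, length(enc_channels) == L, kernel %% 2 == 1,
            d_model %% heads == 0)
  structure(list(L = L, enc_channels = as.integer(enc_channels),
                 kernel = as.integer(kernel), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), heads = as.integer(heads),
                 ffn = as.integer(ffn), dropout = dropout,
                 max_tokens = as.integer(max_tokens)),
            class = "generator_config")
}

#' Initialize generator parameters
#' @param cfg a \code{\link{generator_config}}
#' @param seed integer seed for weight initialization
#' @return a generator model object (environment with layers and \code{params})
#' @export
generator_init <- function(cfg = generator_config(), seed = 1L) {
  with_seed(seed, {
    g <- new.env(parent = emptyenv())
    g$cfg <- cfg
    L <- cfg$L; ch <- cfg$enc_channels
    in_ch <- c(1L, ch[-L])
    g$enc <- lapply(seq_len(L), function(i)
      make_conv1d(in_ch[i], ch[i], cfg$kernel, 2L, sprintf("enc%d", i)))
    g$bott_in <- make_conv1d(ch[L], 2L * ch[L], 1L, 1L, "bott_in")
    g$tok_in <- make_dense(2L * ch[L], cfg$d_model, "tok_in")
    g$pos <- ad_param(matrix(stats::rnorm(cfg$max_tokens * cfg$d_model, sd = 0.02),
                             cfg$max_tokens, cfg$d_model), "gen.pos")
    g$blocks <- lapply(seq_len(cfg$n_layers), function(i)
      make_tblock(cfg$d_model, cfg$heads, cfg$ffn, sprintf("gen.tb%d", i)))
    g$tok_out <- make_dense(cfg$d_model, 2L * ch[L], "tok_out")
    g$bott_out <- make_conv1d(2L * ch[L], ch[L], 1L, 1L, "bott_out")
    # decoder stage i upsamples x2; merge conv combines the mirrored skip
    tch <- c(ch[L], rev(ch)[-1])            # tconv output channels per stage
    skip_ch <- c(rev(ch)[-1], 1L)           # channels of the concatenated skip
    target <- c(rev(ch)[-1], 1L)            # merge conv output channels
    g$dec_up <- lapply(seq_len(L), function(i) {
      prev <- if (i == 1L) ch[L] else target[i - 1L]
      make_tconv1d(prev, tch[i], cfg$kernel, sprintf("dec_up%d", i))
    })
    g$dec_merge <- lapply(seq_len(L), function(i)
      make_conv1d(tch[i] + skip_ch[i], target[i], cfg$kernel, 1L,
                  sprintf("dec_merge%d", i)))
    g$params <- c(
      do.call(c, lapply(g$enc, `[[`, "params")),
      g$bott_in$params, g$tok_in$params, list(g$pos),
      do.call(c, lapply(g$blocks, `[[`, "params")),
      g$tok_out$params, g$bott_out$params,
      do.call(c, lapply(g$dec_up, `[[`, "params")),
      do.call(c, lapply(g$dec_merge, `[[`, "params")))
    g$mask_cache <- new.env(parent = emptyenv())
    g
  })
}

# batch matrix (B x L) -> sample-major (B*L) x 1
batch_to_node_rows <- function(x) matrix(as.numeric(t(x)), ncol = 1L)

node_rows_to_batch <- function(v, B, L) matrix(v, B, L, byrow = TRUE)

#' Generator forward pass: normalized PPG windows to normalized ECG windows
#'
#' Input length is padded to a multiple of \code{2^L} and the output cropped
#' back, so output length always equals input length; the Tanh head keeps all
#' values in (-1, 1).
#'
#' @param p numeric vector, B x L matrix, or an autodiff node ((B*L) x 1)
#' @param gen model from \code{\link{generator_init}}
#' @param train enable dropout
#' @param B,L batch size and window length (required when \code{p} is a node)
#' @return for numeric input, a numeric vector/matrix of matching shape; for
#'   node input, the output node
#' @export
generator_forward <- function(p, gen, train = FALSE, B = NULL, L = NULL) {
  cfg <- gen$cfg
  numeric_in <- !ad_is_node(p)
  if (numeric_in) {
    if (is.null(dim(p))) p <- matrix(p, 1L)
    if (length(p) == 0) stop("empty input")
    B <- nrow(p); L <- ncol(p)
    x <- ad_const(batch_to_node_rows(p))
  } else {
    stopifnot(!is.null(B), !is.null(L))
    x <- p
  }
  div <- 2L^cfg$L
  Lp <- as.integer(ceiling(L / div) * div)
  if (Lp != L) {
    # replicate-pad each sample's tail via row gather
    src <- unlist(lapply(seq_len(B), function(b)
      c((b - 1L) * L + seq_len(L), rep((b - 1L) * L + L, Lp - L))))
    x <- rows_gather(x, src)
  }
  lens <- Lp
  h <- x
  skips <- vector("list", cfg$L + 1L)
  skips[[cfg$L + 1L]] <- x                       # input itself, used by last stage
  for (i in seq_len(cfg$L)) {
    h <- ad_relu(gen$enc[[i]]$fwd(h, B, lens))
    lens <- lens %/% 2L
    skips[[i]] <- h                               # stored at its own depth
  }
  # bottleneck
  Lb <- lens
  h <- ad_relu(gen$bott_in$fwd(h, B, Lb))
  tok <- gen$tok_in$fwd(h)
  if (Lb > cfg$max_tokens) stop("window produces more tokens than max_tokens")
  pos <- rows_gather(gen$pos, rep(seq_len(Lb), times = B))
  tok <- ad_add(tok, pos)
  mkey <- paste0(B, "x", Lb)
  mask <- gen$mask_cache[[mkey]]
  if (is.null(mask)) {
    mask <- attn_mask(B, Lb, causal = TRUE)
    gen$mask_cache[[mkey]] <- mask
  }
  for (blk in gen$blocks) tok <- blk$fwd(tok, mask, cfg$dropout, train)
  h <- gen$tok_out$fwd(tok)
  h <- ad_relu(gen$bott_out$fwd(h, B, Lb))
  # decoder with skip concatenation at mirrored depths
  for (i in seq_len(cfg$L)) {
    h <- gen$dec_up[[i]]$fwd(h, B, lens)
    lens <- lens * 2L
    skip <- if (i < cfg$L) skips[[cfg$L - i]] else skips[[cfg$L + 1L]]
    h <- ad_cbind2(h, skip)
    h <- gen$dec_merge[[i]]$fwd(h, B, lens)
    if (i < cfg$L) h <- ad_relu(h)
  }
  out <- ad_tanh(h)
  if (Lp != L) {
    keep <- unlist(lapply(seq_len(B), function(b) (b - 1L) * Lp + seq_len(L)))
    out <- rows_gather(out, keep)
  }
  if (numeric_in) {
    y <- node_rows_to_batch(out$v[, 1L], B, L)
    if (B == 1L) as.numeric(y) else y
  } else out
}

# ---- critic / discriminator -------------------------------------------------

#' Critic (discriminator) architecture configuration
#'
#' Three stride-1 convolutions (kernels 65/33/17, channels 64/128/256 by
#' default, layer norm after the first layer and at the encoder output) feed
#' \code{tokens} average-pooled steps projected to \code{d_model}; a CLS token
#' plus learned positions run through a 2-layer, 2-head Transformer. The
#' critic head is FC \code{fc_embed} -> \code{fc_hidden} -> scalar (unbounded);
#' the pretext head is a shared 128-128 trunk with six binary logits. A
#' masked-point head (d_model/2 = 128) is constructed for architectural
#' completeness but unused by default.
#'
#' @param conv_kernels,conv_channels three-element conv stacks
#' @param d_model,n_layers,heads,ffn Transformer dimensions
#' @param tokens number of pooled token steps
#' @param fc_embed,fc_hidden critic head widths (embedding = fc_embed activation)
#' @param trunk pretext trunk width
#' @param masked_head_dim masked-point head width
#' @param dropout Transformer dropout
#' @return a \code{discriminator_config}
#' @export
discriminator_config <- function(conv_kernels = c(65L, 33L, 17L),
                                 conv_channels = c(64L, 128L, 256L),
                                 d_model = 256L, n_layers = 2L, heads = 2L,
                                 ffn = 2L * d_model, tokens = 64L,
                                 fc_embed = 512L, fc_hidden = 256L,
                                 trunk = 128L, masked_head_dim = 128L,
                                 dropout = 0.2) {
  stopifnot(length(conv_kernels) == 3, length(conv_channels) == 3,
            d_model %% heads == 0, ffn == 2L * d_model)
  structure(list(conv_kernels = as.integer(conv_kernels),
                 conv_channels = as.integer(conv_channels),
                 d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 heads = as.integer(heads), ffn = as.integer(ffn),
                 tokens = as.integer(tokens), fc_embed = as.integer(fc_embed),
                 fc_hidden = as.integer(fc_hidden), trunk = as.integer(trunk),
                 masked_head_dim = as.integer(masked_head_dim),
                 dropout = dropout),
            class = "discriminator_config")
}

#' Initialize critic parameters
#' @param cfg a \code{\link{discriminator_config}}
#' @param seed integer seed
#' @return critic model object; \code{$transformer_params} marks the tensors
#'   frozen during adversarial fine-tuning
#' @export
discriminator_init <- function(cfg = discriminator_config(), seed = 1L) {
  with_seed(seed, {
    d <- new.env(parent = emptyenv())
    d$cfg <- cfg
    ck <- cfg$conv_kernels; cc <- cfg$conv_channels
    d$conv1 <- make_conv1d(1L, cc[1], ck[1], 1L, "d.conv1")
    d$ln1 <- make_layernorm(cc[1], "d.ln1")
    d$conv2 <- make_conv1d(cc[1], cc[2], ck[2], 1L, "d.conv2")
    d$conv3 <- make_conv1d(cc[2], cc[3], ck[3], 1L, "d.conv3")
    d$ln_out <- make_layernorm(cc[3], "d.lnout")
    d$proj <- make_dense(cc[3], cfg$d_model, "d.proj")
    d$cls <- ad_param(matrix(stats::rnorm(cfg$d_model, sd = 0.02), 1L), "d.cls")
    d$pos <- ad_param(matrix(stats::rnorm((cfg$tokens + 1L) * cfg$d_model, sd = 0.02),
                             cfg$tokens + 1L, cfg$d_model), "d.pos")
    d$ln_z <- make_layernorm(cfg$d_model, "d.lnz")
    d$blocks <- lapply(seq_len(cfg$n_layers), function(i)
      make_tblock(cfg$d_model, cfg$heads, cfg$ffn, sprintf("d.tb%d", i)))
    d$fc1 <- make_dense(cfg$d_model, cfg$fc_embed, "d.fc1")
    d$fc2 <- make_dense(cfg$fc_embed, cfg$fc_hidden, "d.fc2")
    d$fc3 <- make_dense(cfg$fc_hidden, 1L, "d.fc3")
    d$trunk1 <- make_dense(cfg$d_model, cfg$trunk, "d.trunk1")
    d$trunk2 <- make_dense(cfg$trunk, cfg$trunk, "d.trunk2")
    d$heads6 <- make_dense(cfg$trunk, 6L, "d.heads6")
    d$masked1 <- make_dense(cfg$d_model, cfg$masked_head_dim, "d.masked1")
    d$masked2 <- make_dense(cfg$masked_head_dim, 1L, "d.masked2")
    d$transformer_params <- c(list(d$cls, d$pos), d$ln_z$params,
                              do.call(c, lapply(d$blocks, `[[`, "params")))
    d$encoder_params <- c(d$conv1$params, d$ln1$params, d$conv2$params,
                          d$conv3$params, d$ln_out$params, d$proj$params)
    d$critic_head_params <- c(d$fc1$params, d$fc2$params, d$fc3$params)
    d$pretext_head_params <- c(d$trunk1$params, d$trunk2$params, d$heads6$params)
    d$params <- c(d$encoder_params, d$transformer_params, d$critic_head_params,
                  d$pretext_head_params, d$masked1$params, d$masked2$params)
    d$mask_cache <- new.env(parent = emptyenv())
    d
  })
}

#' Critic forward pass
#'
#' In \code{critic} mode returns one unbounded real score per window plus the
#' penultimate-FC embedding (width \code{fc_embed}); in \code{pretext} mode
#' returns six binary logits per window.
#'
#' @param x numeric vector, B x L matrix, or node ((B*L) x 1)
#' @param disc model from \code{\link{discriminator_init}}
#' @param mode \code{"critic"} or \code{"pretext"}
#' @param train enable dropout
#' @param B,L batch shape, required for node input
#' @return list with \code{out} (node: B x 1 scores or B x 6 logits),
#'   \code{embedding} (node, critic mode), \code{cls} (node)
#' @export
discriminator_forward <- function(x, disc, mode = c("critic", "pretext"),
                                  train = FALSE, B = NULL, L = NULL) {
  mode <- match.arg(mode)
  cfg <- disc$cfg
  if (!ad_is_node(x)) {
    if (is.null(dim(x))) x <- matrix(x, 1L)
    B <- nrow(x); L <- ncol(x)
    x <- ad_const(batch_to_node_rows(x))
  } else stopifnot(!is.null(B), !is.null(L))
  h <- disc$ln1$fwd(ad_relu(disc$conv1$fwd(x, B, L)))
  h <- ad_relu(disc$conv2$fwd(h, B, L))
  h <- disc$ln_out$fwd(ad_relu(disc$conv3$fwd(h, B, L)))
  s <- cfg$tokens
  pkey <- paste0(B, "x", L)
  P <- disc$mask_cache[[paste0("pool", pkey)]]
  if (is.null(P)) {
    P <- pool_matrix(B, L, s)
    disc$mask_cache[[paste0("pool", pkey)]] <- P
  }
  tok <- disc$proj$fwd(ad_matmul(ad_const(P), h))          # B*s x d
  # interleave CLS first within each sample: rows (b-1)*(s+1)+1 = CLS
  cls_tile <- rows_gather(disc$cls, rep(1L, B))            # B x d
  stacked <- ad_rbind2(cls_tile, tok)                      # (B + B*s) x d
  src <- unlist(lapply(seq_len(B), function(b) c(b, B + (b - 1L) * s + seq_len(s))))
  z <- rows_gather(stacked, src)                           # B*(s+1) x d
  pos <- rows_gather(disc$pos, rep(seq_len(s + 1L), times = B))
  z <- disc$ln_z$fwd(ad_add(z, pos))
  mkey <- paste0("attn", B)
  mask <- disc$mask_cache[[mkey]]
  if (is.null(mask)) {
    mask <- attn_mask(B, s + 1L, causal = FALSE)
    disc$mask_cache[[mkey]] <- mask
  }
  for (blk in disc$blocks) z <- blk$fwd(z, mask, cfg$dropout, train)
  cls <- rows_gather(z, (seq_len(B) - 1L) * (s + 1L) + 1L)  # B x d
  if (mode == "critic") {
    emb <- ad_relu(disc$fc1$fwd(cls))
    hid <- ad_relu(disc$fc2$fwd(emb))
    list(out = disc$fc3$fwd(hid), embedding = emb, cls = cls)
  } else {
    tr <- ad_relu(disc$trunk2$fwd(ad_relu(disc$trunk1$fwd(cls))))
    list(out = disc$heads6$fwd(tr), embedding = tr, cls = cls)
  }
}

# ---- AF classifiers ---------------------------------------------------------

# extend an LSTM layer to emit the per-step hidden sequence
lstm_seq <- function(ly, xs, B) {
  h <- ad_const(matrix(0, B, ly$nh)); cc <- ad_const(matrix(0, B, ly$nh))
  out <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    z <- ad_bias(ad_add(ad_matmul(xs[[t]], ly$W), ad_matmul(h, ly$U)), ly$b)
    nh <- ly$nh
    i <- ad_sigmoid(ad_cols(z, 1L, nh))
    f <- ad_sigmoid(ad_cols(z, nh + 1L, 2L * nh))
    o <- ad_sigmoid(ad_cols(z, 2L * nh + 1L, 3L * nh))
    g <- ad_tanh(ad_cols(z, 3L * nh + 1L, 4L * nh))
    cc <- ad_add(ad_mul(f, cc), ad_mul(i, g))
    h <- ad_mul(o, ad_tanh(cc))
    out[[t]] <- h
  }
  out
}

#' Bidirectional-LSTM AF classifier configuration and initialization
#'
#' Two stacked LSTM layers (bidirectional: forward and backward passes
#' concatenated), dropout, then two ReLU fully connected layers and a
#' sigmoid probability head.
#'
#' @param hidden LSTM hidden units per direction (default 128)
#' @param fc fully connected width (default 256)
#' @param dropout dropout probability (default 0.5)
#' @param seed integer seed
#' @return classifier model object
#' @export
bidlstm_init <- function(hidden = 128L, fc = 256L, dropout = 0.5, seed = 1L) {
  with_seed(seed, {
    m <- new.env(parent = emptyenv())
    m$hidden <- hidden; m$dropout <- dropout; m$type <- "bidlstm"
    m$f1 <- make_lstm(1L, hidden, "bl.f1"); m$b1 <- make_lstm(1L, hidden, "bl.b1")
    m$f2 <- make_lstm(2L * hidden, hidden, "bl.f2")
    m$b2 <- make_lstm(2L * hidden, hidden, "bl.b2")
    m$fc1 <- make_dense(2L * hidden, fc, "bl.fc1")
    m$fc2 <- make_dense(fc, fc, "bl.fc2")
    m$out <- make_dense(fc, 1L, "bl.out")
    m$params <- c(m$f1$params, m$b1$params, m$f2$params, m$b2$params,
                  m$fc1$params, m$fc2$params, m$out$params)
    m
  })
}

#' AF classifier forward pass (probability of atrial fibrillation)
#'
#' @param x numeric B x T matrix of normalized ECG segments (or vector)
#' @param model from \code{\link{bidlstm_init}} or \code{\link{cnnlstm_init}}
#' @param train enable dropout
#' @return list with \code{prob} (node, B x 1 in [0, 1])
#' @export
classifier_forward <- function(x, model, train = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  B <- nrow(x); TT <- ncol(x)
  if (model$type == "cnnlstm") {
    xin <- ad_const(batch_to_node_rows(x))
    h <- ad_relu(model$conv1$fwd(xin, B, TT)); TT <- model$conv1$len_out(TT)
    r <- maxpool2(h, B, TT); h <- r$x; TT <- r$L
    h <- ad_relu(model$conv2$fwd(h, B, TT)); TT <- model$conv2$len_out(TT)
    r <- maxpool2(h, B, TT); h <- r$x; TT <- r$L
    xs <- lapply(seq_len(TT), function(t)
      rows_gather(h, (seq_len(B) - 1L) * TT + t))
  } else {
    xn <- ad_const(x)
    xs <- lapply(seq_len(TT), function(t) ad_cols(xn, t, t))
  }
  s1f <- lstm_seq(model$f1, xs, B)
  s1b <- rev(lstm_seq(model$b1, rev(xs), B))
  seq1 <- mapply(ad_cbind2, s1f, s1b, SIMPLIFY = FALSE)
  h2f <- model$f2$fwd(seq1, B)
  h2b <- model$b2$fwd(rev(seq1), B)
  h <- ad_cbind2(h2f, h2b)
  if (train && model$dropout > 0) {
    keep <- (matrix(stats::runif(length(h$v)), nrow(h$v)) > model$dropout) /
      (1 - model$dropout)
    h <- ad_cmul(h, keep)
  }
  h <- ad_relu(model$fc1$fwd(h))
  h <- ad_relu(model$fc2$fwd(h))
  list(prob = ad_sigmoid(model$out$fwd(h)))
}

# max pooling (size 2, stride 2) over the time dimension via the relu trick
maxpool2 <- function(x, B, L) {
  L2 <- L %/% 2L
  a <- rows_gather(x, unlist(lapply(seq_len(B), function(b)
    (b - 1L) * L + 2L * seq_len(L2) - 1L)))
  b2 <- rows_gather(x, unlist(lapply(seq_len(B), function(b)
    (b - 1L) * L + 2L * seq_len(L2))))
  list(x = ad_add(a, ad_relu(ad_sub(b2, a))), L = L2)
}

#' CNN+LSTM AF classifier initialization
#'
#' Two Conv1D (kernel 4, ReLU) + max-pool (2, 2) stages quartering the
#' temporal dimension, followed by the same bidirectional LSTM / FC stack as
#' the Bid-LSTM model.
#'
#' @param filters conv filters (equal to the LSTM input dimensionality)
#' @inheritParams bidlstm_init
#' @return classifier model object
#' @export
cnnlstm_init <- function(hidden = 128L, fc = 256L, filters = 16L,
                         dropout = 0.5, seed = 1L) {
  with_seed(seed, {
    m <- new.env(parent = emptyenv())
    m$hidden <- hidden; m$dropout <- dropout; m$type <- "cnnlstm"
    m$conv1 <- make_conv1d(1L, filters, 4L, 1L, "cl.conv1")
    m$conv2 <- make_conv1d(filters, filters, 4L, 1L, "cl.conv2")
    m$f1 <- make_lstm(filters, hidden, "cl.f1")
    m$b1 <- make_lstm(filters, hidden, "cl.b1")
    m$f2 <- make_lstm(2L * hidden, hidden, "cl.f2")
    m$b2 <- make_lstm(2L * hidden, hidden, "cl.b2")
    m$fc1 <- make_dense(2L * hidden, fc, "cl.fc1")
    m$fc2 <- make_dense(fc, fc, "cl.fc2")
    m$out <- make_dense(fc, 1L, "cl.out")
    m$params <- c(m$conv1$params, m$conv2$params, m$f1$params, m$b1$params,
                  m$f2$params, m$b2$params, m$fc1$params, m$fc2$params,
                  m$out$params)
    m
  })
}

# ---- checkpoints ------------------------------------------------------------

#' Save model parameters to a checkpoint file
#'
#' The checkpoint stores a JSON-encoded header (config echo, seed, epoch)
#' alongside the parameter values.
#'
#' @param model a model object with a \code{$params} list and \code{$cfg}
#' @param path output file
#' @param seed,epoch provenance recorded in the header
#' @export
save_checkpoint <- function(model, path, seed = NA_integer_, epoch = NA_integer_) {
  header <- jsonlite::toJSON(list(config = unclass(model$cfg), seed = seed,
                                  epoch = epoch, n_params = n_params(model$params)),
                             auto_unbox = TRUE, null = "null")
  saveRDS(list(header = as.character(header),
               values = lapply(model$params, function(p) p$v)), path)
}

#' Load parameter values from a checkpoint into a compatible model
#' @param model target model (architecture must match)
#' @param path checkpoint file
#' @return the model, with the decoded header attached as \code{$ckpt_header}
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  stopifnot(length(ck$values) == length(model$params))
  for (i in seq_along(ck$values)) {
    stopifnot(all(dim(ck$values[[i]]) == dim(model$params[[i]]$v)))
    model$params[[i]]$v <- ck$values[[i]]
  }
  model$ckpt_header <- jsonlite::fromJSON(ck$header)
  model
}

#' Parameter counts per submodule of a model
#' @param model generator or critic model object
#' @return named numeric vector of parameter counts
#' @export
inspect_model <- function(model) {
  if (!is.null(model$enc)) {
    c(encoder = n_params(do.call(c, lapply(model$enc, `[[`, "params"))),
      bottleneck = n_params(c(model$bott_in$params, model$tok_in$params,
                              list(model$pos),
                              do.call(c, lapply(model$blocks, `[[`, "params")),
                              model$tok_out$params, model$bott_out$params)),
      decoder = n_params(c(do.call(c, lapply(model$dec_up, `[[`, "params")),
                           do.call(c, lapply(model$dec_merge, `[[`, "params")))),
      total = n_params(model$params))
  } else {
    c(encoder = n_params(model$encoder_params),
      transformer = n_params(model$transformer_params),
      critic_head = n_params(model$critic_head_params),
      pretext_head = n_params(model$pretext_head_params),
      total = n_params(model$params))
  }
}
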