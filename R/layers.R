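# Neural-network layers for 1-D physiological signals.
#
# Data layout convention: a batch of B signals of length L with C channels is
# a (B*L) x C matrix, rows sample-major (sample 1 positions 1..L, then
# sample 2, ...). Convolutions are realized as a cached patch-gather (im2col)
# followed by one dense matrix product, so a whole batch is a single matmul.

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

make_dense <- function(nin, nout, name = "dense") {
  ly <- new.env(parent = emptyenv())
  ly$W <- ad_param(glorot(nin, nout), paste0(name, ".W"))
  ly$b <- ad_param(matrix(0, 1L, nout), paste0(name, ".b"))
  ly$params <- list(ly$W, ly$b)
  ly$fwd <- function(x) ad_bias(ad_matmul(x, ly$W), ly$b)
  ly
}

# patch-gather indices for conv1d with "same" odd-kernel padding
im2col_idx <- function(B, L, C, K, stride) {
  pad <- (K - 1L) %/% 2L
  Lout <- (L + 2L * pad - K) %/% stride + 1L
  n <- B * Lout
  t_out <- rep(seq_len(Lout), times = B)
  b_of <- rep(seq_len(B), each = Lout)
  k_of <- rep(seq_len(K), each = C)
  c_of <- rep(seq_len(C), times = K)
  t_in <- outer((t_out - 1L) * stride - pad, k_of, "+")  # n x K*C
  flat <- t(t((b_of - 1L) * L + t_in) + (c_of - 1L) * (B * L))
  flat[t_in < 1L | t_in > L] <- 0L
  storage.mode(flat) <- "integer"
  flat
}

make_conv1d <- function(in_ch, out_ch, K, stride = 1L, name = "conv") {
  ly <- new.env(parent = emptyenv())
  ly$K <- K; ly$stride <- stride; ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$W <- ad_param(glorot(K * in_ch, out_ch), paste0(name, ".W"))
  ly$b <- ad_param(matrix(0, 1L, out_ch), paste0(name, ".b"))
  ly$params <- list(ly$W, ly$b)
  ly$cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, B, L) {
    key <- paste0(B, "x", L)
    idx <- ly$cache[[key]]
    if (is.null(idx)) {
      idx <- im2col_idx(B, L, in_ch, K, stride)
      ly$cache[[key]] <- idx
    }
    ad_bias(ad_matmul(ad_gather(x, idx), ly$W), ly$b)
  }
  ly$len_out <- function(L) (L + 2L * ((K - 1L) %/% 2L) - K) %/% stride + 1L
  ly
}

# zero-insertion x2 upsampling indices (odd output positions copy the input)
upsample2_idx <- function(B, L, C) {
  u <- seq_len(2L * L)
  per_sample <- ifelse(u %% 2L == 1L, (u + 1L) %/% 2L, 0L)
  rows <- unlist(lapply(seq_len(B), function(b)
    ifelse(per_sample > 0L, (b - 1L) * L + per_sample, 0L)))
  idx <- sapply(seq_len(C), function(c) ifelse(rows > 0L, (c - 1L) * (B * L) + rows, 0L))
  idx <- matrix(as.integer(idx), ncol = C)
  idx
}

# transposed (fractionally strided) convolution: zero-insertion then conv
make_tconv1d <- function(in_ch, out_ch, K, name = "tconv") {
  ly <- new.env(parent = emptyenv())
  ly$conv <- make_conv1d(in_ch, out_ch, K, 1L, name)
  ly$params <- ly$conv$params
  ly$cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, B, L) {
    key <- paste0(B, "x", L)
    idx <- ly$cache[[key]]
    if (is.null(idx)) {
      idx <- upsample2_idx(B, L, in_ch)
      ly$cache[[key]] <- idx
    }
    up <- ad_smul(ad_gather(x, idx), 2)  # keep expected magnitude after zero fill
    ly$conv$fwd(up, B, 2L * L)
  }
  ly
}

make_layernorm <- function(d, name = "ln") {
  ly <- new.env(parent = emptyenv())
  ly$gamma <- ad_param(matrix(1, 1L, d), paste0(name, ".g"))
  ly$beta <- ad_param(matrix(0, 1L, d), paste0(name, ".b"))
  ly$params <- list(ly$gamma, ly$beta)
  ly$fwd <- function(x) ad_layernorm(x, ly$gamma, ly$beta)
  ly
}

# additive attention mask: block-diagonal over batch, optionally causal
attn_mask <- function(B, s, causal) {
  n <- B * s
  m <- matrix(-1e9, n, n)
  for (b in seq_len(B)) {
    r <- ((b - 1L) * s + 1L):(b * s)
    blk <- matrix(0, s, s)
    if (causal) blk[upper.tri(blk)] <- -1e9
    m[r, r] <- blk
  }
  m
}

make_mha <- function(d, heads, name = "mha") {
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  ly <- new.env(parent = emptyenv())
  ly$Wq <- ad_param(glorot(d, d), paste0(name, ".Wq"))
  ly$Wk <- ad_param(glorot(d, d), paste0(name, ".Wk"))
  ly$Wv <- ad_param(glorot(d, d), paste0(name, ".Wv"))
  ly$Wo <- ad_param(glorot(d, d), paste0(name, ".Wo"))
  ly$params <- list(ly$Wq, ly$Wk, ly$Wv, ly$Wo)
  ly$fwd <- function(x, mask) {
    q <- ad_matmul(x, ly$Wq); k <- ad_matmul(x, ly$Wk); v <- ad_matmul(x, ly$Wv)
    outs <- NULL
    for (h in seq_len(heads)) {
      cs <- ((h - 1L) * dh + 1L); ce <- h * dh
      qh <- ad_cols(q, cs, ce); kh <- ad_cols(k, cs, ce); vh <- ad_cols(v, cs, ce)
      sc <- ad_smul(ad_matmul(qh, ad_t(kh)), 1 / sqrt(dh))
      a <- ad_softmax_rows(ad_cadd(sc, mask))
      oh <- ad_matmul(a, vh)
      outs <- if (is.null(outs)) oh else ad_cbind2(outs, oh)
    }
    ad_matmul(outs, ly$Wo)
  }
  ly
}

# pre-norm Transformer encoder block with GELU MLP
make_tblock <- function(d, heads, ffn, name = "tb") {
  ly <- new.env(parent = emptyenv())
  ly$ln1 <- make_layernorm(d, paste0(name, ".ln1"))
  ly$mha <- make_mha(d, heads, paste0(name, ".mha"))
  ly$ln2 <- make_layernorm(d, paste0(name, ".ln2"))
  ly$fc1 <- make_dense(d, ffn, paste0(name, ".fc1"))
  ly$fc2 <- make_dense(ffn, d, paste0(name, ".fc2"))
  ly$params <- c(ly$ln1$params, ly$mha$params, ly$ln2$params,
                 ly$fc1$params, ly$fc2$params)
  ly$fwd <- function(x, mask, dropout = 0, train = FALSE) {
    x <- ad_add(x, ly$mha$fwd(ly$ln1$fwd(x), mask))
    h <- ly$fc2$fwd(ad_gelu(ly$fc1$fwd(ly$ln2$fwd(x))))
    if (train && dropout > 0) {
      keep <- (matrix(stats::runif(length(h$v)), nrow(h$v)) > dropout) / (1 - dropout)
      h <- ad_cmul(h, keep)
    }
    ad_add(x, h)
  }
  ly
}

# single-direction LSTM; input given as a (B x T) node sliced per step
make_lstm <- function(nin, nh, name = "lstm") {
  ly <- new.env(parent = emptyenv())
  ly$W <- ad_param(glorot(nin, 4L * nh), paste0(name, ".W"))
  ly$U <- ad_param(glorot(nh, 4L * nh), paste0(name, ".U"))
  ly$b <- ad_param(matrix(0, 1L, 4L * nh), paste0(name, ".b"))
  ly$params <- list(ly$W, ly$U, ly$b)
  ly$nh <- nh
  # xs: list of T nodes, each B x nin; returns final hidden state (B x nh)
  ly$fwd <- function(xs, B) {
    h <- ad_const(matrix(0, B, nh)); cc <- ad_const(matrix(0, B, nh))
    for (t in seq_along(xs)) {
      z <- ad_bias(ad_add(ad_matmul(xs[[t]], ly$W), ad_matmul(h, ly$U)), ly$b)
      i <- ad_sigmoid(ad_cols(z, 1L, nh))
      f <- ad_sigmoid(ad_cols(z, nh + 1L, 2L * nh))
      o <- ad_sigmoid(ad_cols(z, 2L * nh + 1L, 3L * nh))
      g <- ad_tanh(ad_cols(z, 3L * nh + 1L, 4L * nh))
      cc <- ad_add(ad_mul(f, cc), ad_mul(i, g))
      h <- ad_mul(o, ad_tanh(cc))
    }
    h
  }
  ly
}

collect_params <- function(...) {
  layers <- list(...)
  out <- list()
  for (ly in layers) out <- c(out, ly$params)
  out
}

n_params <- function(params) sum(vapply(params, function(p) length(p$v), numeric(1)))
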