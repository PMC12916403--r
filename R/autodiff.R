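# Reverse-mode automatic differentiation on dense matrices.
#
# Every value is a numeric matrix wrapped in an environment ("node"). Each
# primitive records a vector-Jacobian product (vjp) closure that itself builds
# nodes, so the graph produced by a backward pass is differentiable again.
# That second-order capability is what allows the Wasserstein critic's
# gradient penalty -- a function of the critic's input gradient -- to be
# optimized by ordinary gradient descent.
#
# The primitive set is deliberately small; everything else (softmax,
# layer normalization, GELU, attention) is composed from it at forward time.

.ad <- new.env(parent = emptyenv())
.ad$gid <- 0L

ad_node <- function(v, parents = list(), vjp = NULL, req = FALSE, op = "const") {
  n <- new.env(parent = emptyenv())
  .ad$gid <- .ad$gid + 1L
  n$gid <- .ad$gid
  n$v <- v
  n$parents <- parents
  n$vjp <- vjp
  n$req <- req
  n$op <- op
  class(n) <- "ad_node"
  n
}

#' @export
print.ad_node <- function(x, ...) {
  cat(sprintf("<ad_node %s %dx%d req=%s>\n", x$op, nrow(x$v), ncol(x$v), x$req))
  invisible(x)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

#' Wrap a numeric matrix as a constant autodiff node
#' @param x numeric vector or matrix
#' @return an \code{ad_node}
#' @export
ad_const <- function(x) ad_node(as_mat(x), op = "const")

#' Create a trainable parameter node (gradients accumulate in \code{$g})
#' @param x initial numeric value
#' @param name label used in diagnostics
#' @return an \code{ad_node} with \code{req = TRUE}
#' @export
ad_param <- function(x, name = "") {
  n <- ad_node(as_mat(x), req = TRUE, op = paste0("param:", name))
  n$g <- matrix(0, nrow(n$v), ncol(n$v))
  n
}

#' Test whether an object is an autodiff node
#' @param x object
#' @export
ad_is_node <- function(x) inherits(x, "ad_node")

wrap <- function(x) if (ad_is_node(x)) x else ad_const(x)

req_any <- function(...) any(vapply(list(...), function(p) p$req, logical(1)))

# ---- arithmetic primitives --------------------------------------------------

#' Elementwise node addition
#' @param a,b nodes or numerics of equal shape
#' @export
ad_add <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  ad_node(a$v + b$v, list(a, b),
          function(g, out) list(g, g),
          req_any(a, b), "add")
}

ad_sub <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  ad_node(a$v - b$v, list(a, b),
          function(g, out) list(g, ad_neg(g)),
          req_any(a, b), "sub")
}

ad_neg <- function(a) {
  a <- wrap(a)
  ad_node(-a$v, list(a), function(g, out) list(ad_neg(g)), a$req, "neg")
}

#' Elementwise node multiplication
#' @param a,b nodes or numerics of equal shape
#' @export
ad_mul <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  ad_node(a$v * b$v, list(a, b),
          function(g, out) list(ad_mul(g, b), ad_mul(g, a)),
          req_any(a, b), "mul")
}

# scalar (plain numeric) multiply / add: constants w.r.t. differentiation
#' Multiply a node by a plain scalar
#' @param a node
#' @param s numeric scalar (treated as a constant)
#' @export
ad_smul <- function(a, s) {
  a <- wrap(a)
  ad_node(a$v * s, list(a), function(g, out) list(ad_smul(g, s)), a$req, "smul")
}

ad_sadd <- function(a, s) {
  a <- wrap(a)
  ad_node(a$v + s, list(a), function(g, out) list(g), a$req, "sadd")
}

# elementwise multiply / add by a constant matrix (e.g. dropout or ReLU masks)
ad_cmul <- function(a, m) {
  a <- wrap(a)
  ad_node(a$v * m, list(a), function(g, out) list(ad_cmul(g, m)), a$req, "cmul")
}

ad_cadd <- function(a, m) {
  a <- wrap(a)
  ad_node(a$v + m, list(a), function(g, out) list(g), a$req, "cadd")
}

#' Matrix product of two nodes
#' @param a,b nodes (conformable matrices)
#' @export
ad_matmul <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  ad_node(a$v %*% b$v, list(a, b),
          function(g, out) list(ad_matmul(g, ad_t(b)), ad_matmul(ad_t(a), g)),
          req_any(a, b), "matmul")
}

ad_t <- function(a) {
  a <- wrap(a)
  ad_node(t(a$v), list(a), function(g, out) list(ad_t(g)), a$req, "t")
}

#' Sum all elements of a node into a 1 x 1 node
#' @param a node
#' @export
ad_sum <- function(a) {
  a <- wrap(a)
  d <- dim(a$v)
  ad_node(matrix(sum(a$v), 1L, 1L), list(a),
          function(g, out) {
            ones_l <- ad_const(matrix(1, d[1L], 1L))
            ones_r <- ad_const(matrix(1, 1L, d[2L]))
            list(ad_matmul(ad_matmul(ones_l, g), ones_r))
          }, a$req, "sum")
}

#' Mean of all elements of a node
#' @param a node
#' @export
ad_mean <- function(a) {
  a <- wrap(a)
  ad_smul(ad_sum(a), 1 / length(a$v))
}

# ---- nonlinearities ---------------------------------------------------------

ad_tanh <- function(a) {
  a <- wrap(a)
  ad_node(tanh(a$v), list(a),
          function(g, out) list(ad_mul(g, ad_sadd(ad_neg(ad_mul(out, out)), 1))),
          a$req, "tanh")
}

ad_exp <- function(a) {
  a <- wrap(a)
  ad_node(exp(a$v), list(a),
          function(g, out) list(ad_mul(g, out)), a$req, "exp")
}

ad_sigmoid <- function(a) {
  a <- wrap(a)
  ad_node(1 / (1 + exp(-a$v)), list(a),
          function(g, out)
            list(ad_mul(g, ad_mul(out, ad_sadd(ad_neg(out), 1)))),
          a$req, "sigmoid")
}

ad_relu <- function(a) {
  a <- wrap(a)
  mask <- (a$v > 0) * 1
  ad_node(a$v * mask, list(a),
          function(g, out) list(ad_cmul(g, mask)), a$req, "relu")
}

ad_softplus <- function(a) {
  a <- wrap(a)
  v <- pmax(a$v, 0) + log1p(exp(-abs(a$v)))
  ad_node(v, list(a),
          function(g, out) list(ad_mul(g, ad_sigmoid(a))), a$req, "softplus")
}

ad_recip <- function(a) {
  a <- wrap(a)
  ad_node(1 / a$v, list(a),
          function(g, out) list(ad_neg(ad_mul(g, ad_mul(out, out)))),
          a$req, "recip")
}

ad_sqrt <- function(a) {
  a <- wrap(a)
  ad_node(sqrt(a$v), list(a),
          function(g, out) list(ad_mul(g, ad_smul(ad_recip(out), 0.5))),
          a$req, "sqrt")
}

# ---- structural primitives --------------------------------------------------

# out[i] = flat(a)[idx[i]], with idx == 0L meaning a structural zero (padding).
# Linear in a, so its vjp (scatter-add) and the scatter's vjp (gather) close
# the pair under differentiation.
ad_gather <- function(a, idx) {
  a <- wrap(a)
  d <- dim(a$v)
  v <- matrix(0, nrow(idx), ncol(idx))
  ok <- idx > 0L
  v[ok] <- a$v[idx[ok]]
  ad_node(v, list(a),
          function(g, out) list(ad_scatter(g, idx, d)), a$req, "gather")
}

ad_scatter <- function(g, idx, d) {
  g <- wrap(g)
  ok <- idx > 0L
  v <- numeric(d[1L] * d[2L])
  if (any(ok)) {
    s <- rowsum(g$v[ok], idx[ok])
    v[as.integer(rownames(s))] <- s[, 1L]
  }
  ad_node(matrix(v, d[1L], d[2L]), list(g),
          function(gg, out) list(ad_gather(gg, idx)), g$req, "scatter")
}

ad_cbind2 <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  na <- ncol(a$v)
  ad_node(cbind(a$v, b$v), list(a, b),
          function(g, out) list(ad_cols(g, 1L, na),
                                ad_cols(g, na + 1L, na + ncol(b$v))),
          req_any(a, b), "cbind")
}

ad_rbind2 <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  na <- nrow(a$v)
  ad_node(rbind(a$v, b$v), list(a, b),
          function(g, out) list(ad_rows(g, 1L, na),
                                ad_rows(g, na + 1L, na + nrow(b$v))),
          req_any(a, b), "rbind")
}

ad_cols <- function(a, from, to) {
  a <- wrap(a)
  nc <- ncol(a$v)
  ad_node(a$v[, from:to, drop = FALSE], list(a),
          function(g, out) list(ad_padcols(g, from, nc)), a$req, "cols")
}

ad_padcols <- function(a, from, total) {
  a <- wrap(a)
  v <- matrix(0, nrow(a$v), total)
  v[, from:(from + ncol(a$v) - 1L)] <- a$v
  ad_node(v, list(a),
          function(g, out) list(ad_cols(g, from, from + ncol(a$v) - 1L)),
          a$req, "padcols")
}

ad_rows <- function(a, from, to) {
  a <- wrap(a)
  nr <- nrow(a$v)
  ad_node(a$v[from:to, , drop = FALSE], list(a),
          function(g, out) list(ad_padrows(g, from, nr)), a$req, "rows")
}

ad_padrows <- function(a, from, total) {
  a <- wrap(a)
  v <- matrix(0, total, ncol(a$v))
  v[from:(from + nrow(a$v) - 1L), ] <- a$v
  ad_node(v, list(a),
          function(g, out) list(ad_rows(g, from, from + nrow(a$v) - 1L)),
          a$req, "padrows")
}

# ---- composed operations ----------------------------------------------------

ad_gelu <- function(a) {
  # tanh approximation; composed from primitives so second derivatives exist
  c0 <- sqrt(2 / pi)
  x3 <- ad_mul(a, ad_mul(a, a))
  inner <- ad_smul(ad_add(a, ad_smul(x3, 0.044715)), c0)
  ad_smul(ad_mul(a, ad_sadd(ad_tanh(inner), 1)), 0.5)
}

# row-wise softmax; the row max is detached (softmax is shift invariant,
# so the detachment leaves all derivatives exact almost everywhere)
ad_softmax_rows <- function(a) {
  a <- wrap(a)
  m <- apply(a$v, 1L, max)
  z <- ad_cadd(a, matrix(-m, nrow(a$v), ncol(a$v)))
  e <- ad_exp(z)
  s <- ad_matmul(e, ad_const(matrix(1, ncol(a$v), 1L)))
  r <- ad_recip(s)
  ad_mul(e, ad_matmul(r, ad_const(matrix(1, 1L, ncol(a$v)))))
}

# layer normalization across columns (features), per row
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- wrap(a)
  n <- nrow(a$v); m <- ncol(a$v)
  ones_m1 <- ad_const(matrix(1 / m, m, 1L))
  ones_1m <- ad_const(matrix(1, 1L, m))
  mu <- ad_matmul(a, ones_m1)                       # n x 1
  cen <- ad_sub(a, ad_matmul(mu, ones_1m))
  varr <- ad_matmul(ad_mul(cen, cen), ones_m1)      # n x 1
  inv <- ad_recip(ad_sqrt(ad_sadd(varr, eps)))
  nrm <- ad_mul(cen, ad_matmul(inv, ones_1m))
  ones_n1 <- ad_const(matrix(1, n, 1L))
  ad_add(ad_mul(nrm, ad_matmul(ones_n1, gamma)), ad_matmul(ones_n1, beta))
}

# broadcast a 1 x m bias across n rows
ad_bias <- function(a, b) {
  a <- wrap(a)
  ad_add(a, ad_matmul(ad_const(matrix(1, nrow(a$v), 1L)), b))
}

# ---- backward pass ----------------------------------------------------------

ad_topo <- function(root) {
  cap <- 1024L
  snode <- vector("list", cap); sstage <- integer(cap)
  order <- vector("list", cap); norder <- 0L
  seen <- new.env(parent = emptyenv())
  sp <- 1L; snode[[1L]] <- root; sstage[1L] <- 1L
  while (sp > 0L) {
    node <- snode[[sp]]; stage <- sstage[sp]; sp <- sp - 1L
    key <- as.character(node$gid)
    if (stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      if (sp + 1L + length(node$parents) > length(snode)) {
        grow <- length(snode)
        snode <- c(snode, vector("list", grow))
        sstage <- c(sstage, integer(grow))
      }
      sp <- sp + 1L; snode[[sp]] <- node; sstage[sp] <- 2L
      for (p in node$parents) {
        if (p$req && is.null(seen[[as.character(p$gid)]])) {
          sp <- sp + 1L; snode[[sp]] <- p; sstage[sp] <- 1L
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  order[seq_len(norder)]
}

#' Differentiate a scalar node with respect to target nodes
#'
#' Returns one gradient node per target; because the backward pass is built
#' from the same primitives, the returned nodes can themselves be part of a
#' further differentiated expression (double backprop).
#'
#' @param root scalar (1 x 1) output node
#' @param targets list of nodes to differentiate with respect to
#' @return list of gradient nodes (zero-valued constants where unreachable)
#' @export
ad_grad <- function(root, targets) {
  stopifnot(length(root$v) == 1L)
  grads <- new.env(parent = emptyenv())
  grads[[as.character(root$gid)]] <- ad_const(matrix(1, 1L, 1L))
  order <- ad_topo(root)
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    g <- grads[[as.character(node$gid)]]
    if (is.null(g) || is.null(node$vjp)) next
    pg <- node$vjp(g, node)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$req || is.null(pg[[j]])) next
      key <- as.character(p$gid)
      cur <- grads[[key]]
      grads[[key]] <- if (is.null(cur)) pg[[j]] else ad_add(cur, pg[[j]])
    }
  }
  lapply(targets, function(tg) {
    g <- grads[[as.character(tg$gid)]]
    if (is.null(g)) ad_const(matrix(0, nrow(tg$v), ncol(tg$v))) else g
  })
}

#' Accumulate numeric gradients of a scalar loss into parameter nodes
#' @keywords internal
ad_backward <- function(root, params) {
  gs <- ad_grad(root, params)
  for (i in seq_along(params)) params[[i]]$g <- params[[i]]$g + gs[[i]]$v
  invisible(NULL)
}

# ---- optimizer --------------------------------------------------------------

#' Adam optimizer state over a flat list of parameter nodes
#' @keywords internal
adam_init <- function(params, lr = 1e-3, beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  stopifnot(beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  list(params = params, lr = lr, b1 = beta1, b2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p$v * 0),
       v = lapply(params, function(p) p$v * 0))
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * p$g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * p$g^2
    mhat <- opt$m[[i]] / (1 - opt$b1^opt$t)
    vhat <- opt$v[[i]] / (1 - opt$b2^opt$t)
    p$v <- p$v - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$g <- p$g * 0
  invisible(NULL)
}

# ---- misc -------------------------------------------------------------------

#' Evaluate code under a temporary RNG seed, restoring the previous state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
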