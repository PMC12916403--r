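# Distributional comparison of real vs generated ECG in critic-embedding
# space: unbiased Gaussian-kernel MMD^2, squared energy distance, permutation
# p-values, and a 2-D stochastic neighbor embedding for visualization.

#' Extract critic embeddings for a set of windows
#'
#' One vector per window from the penultimate fully connected activation of
#' the critic head (width \code{fc_embed}, 512 in the default configuration).
#'
#' @param disc critic model
#' @param windows numeric matrix (one window per row) or list of windows
#' @return n x fc_embed numeric matrix
#' @export
extract_embeddings <- function(disc, windows) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- as_batch(windows)
  fw <- discriminator_forward(windows, disc, mode = "critic")
  fw$embedding$v
}

# squared Euclidean distances computed by explicit differences (no
# norm-expansion cancellation, so small distances keep full precision)
pairwise_sq <- function(X, Y) {
  out <- matrix(0, nrow(X), nrow(Y))
  for (j in seq_len(ncol(X))) out <- out + outer(X[, j], Y[, j], "-")^2
  out
}

#' Median-heuristic Gaussian kernel bandwidth
#' @param X,Y numeric matrices (rows are points)
#' @return median pairwise Euclidean distance over the pooled sample
#' @export
median_bandwidth <- function(X, Y) {
  Z <- rbind(X, Y)
  d2 <- pairwise_sq(Z, Z)
  d <- sqrt(pmax(d2[upper.tri(d2)], 0))
  bw <- stats::median(d)
  if (bw == 0) stop("zero bandwidth: all points identical")
  bw
}

#' Unbiased squared maximum mean discrepancy (Gaussian kernel)
#'
#' U-statistic estimator with within-sample diagonals excluded; for equal
#' sample sizes the paired cross-term diagonal is excluded as well, so two
#' identical multisets give exactly 0. The estimate may be slightly negative
#' under the null.
#'
#' @param X,Y numeric matrices with >= 2 rows each
#' @param bw kernel bandwidth; NULL uses the median heuristic on the pool
#' @return scalar MMD^2 estimate
#' @export
mmd2 <- function(X, Y, bw = NULL) {
  X <- as_batch(X); Y <- as_batch(Y)
  n <- nrow(X); m <- nrow(Y)
  stopifnot(n >= 2, m >= 2)
  if (is.null(bw)) bw <- median_bandwidth(X, Y)
  k <- function(A, B) exp(-pairwise_sq(A, B) / (2 * bw^2))
  kxx <- k(X, X); kyy <- k(Y, Y); kxy <- k(X, Y)
  cross <- if (n == m) {
    2 * (sum(kxy) - sum(diag(kxy))) / (n * (n - 1))
  } else 2 * mean(kxy)
  (sum(kxx) - sum(diag(kxx))) / (n * (n - 1)) +
    (sum(kyy) - sum(diag(kyy))) / (m * (m - 1)) - cross
}

#' Squared energy distance between two samples
#'
#' \code{2 E||x - y|| - E||x - x'|| - E||y - y'||} with the V-statistic
#' (all-pairs) expectations.
#'
#' @param X,Y numeric matrices with >= 2 rows each
#' @return scalar energy-distance estimate
#' @export
energy_distance2 <- function(X, Y) {
  X <- as_batch(X); Y <- as_batch(Y)
  stopifnot(nrow(X) >= 2, nrow(Y) >= 2)
  exy <- mean(sqrt(pmax(pairwise_sq(X, Y), 0)))
  exx <- mean(sqrt(pmax(pairwise_sq(X, X), 0)))
  eyy <- mean(sqrt(pmax(pairwise_sq(Y, Y), 0)))
  2 * exy - exx - eyy
}

#' Permutation p-value for a two-sample statistic
#'
#' Pools the samples, re-splits preserving the group sizes \code{n_perm}
#' times, and returns \code{(1 + #(perm >= observed)) / (1 + n_perm)}.
#'
#' @param statistic_fn function (X, Y) -> scalar
#' @param X,Y numeric matrices
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed
#' @return list: \code{p}, \code{observed}, \code{perm} (null draws)
#' @export
permutation_pvalue <- function(statistic_fn, X, Y, n_perm = 1000L, seed = 1L) {
  X <- as_batch(X); Y <- as_batch(Y)
  stopifnot(n_perm >= 99)
  pool <- rbind(X, Y)
  if (nrow(unique(pool)) < 2) stop("degenerate pool")
  n <- nrow(X)
  obs <- statistic_fn(X, Y)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(pool))
    statistic_fn(pool[idx[seq_len(n)], , drop = FALSE],
                 pool[idx[-seq_len(n)], , drop = FALSE])
  }, numeric(1)))
  list(p = (1 + sum(perm >= obs)) / (1 + n_perm), observed = obs, perm = perm)
}

#' Two-sample report on embeddings
#'
#' Computes MMD^2 and squared energy distance with permutation p-values and
#' permutation-resampling SDs.
#'
#' @param X,Y embedding matrices (rows are windows)
#' @param n_perm permutations
#' @param seed integer seed
#' @return named list: mmd2, mmd2_sd, p_mmd, ed2, ed2_sd, p_ed
#' @export
distribution_report <- function(X, Y, n_perm = 1000L, seed = 1L) {
  bw <- median_bandwidth(as_batch(X), as_batch(Y))
  mm <- permutation_pvalue(function(a, b) mmd2(a, b, bw = bw), X, Y, n_perm, seed)
  ee <- permutation_pvalue(energy_distance2, X, Y, n_perm, seed + 1L)
  list(mmd2 = mm$observed, mmd2_sd = stats::sd(mm$perm), p_mmd = mm$p,
       ed2 = ee$observed, ed2_sd = stats::sd(ee$perm), p_ed = ee$p)
}

#' 2-D t-SNE projection for visualization
#'
#' Exact (O(n^2)) t-distributed stochastic neighbor embedding with the
#' defaults used for the embedding scatter plots (perplexity 50, learning
#' rate 600). Visualization only: no exactness contract.
#'
#' @param X numeric matrix (rows are points; n > 3 * perplexity)
#' @param perplexity neighborhood size parameter
#' @param learning_rate gradient step size
#' @param n_iter iterations
#' @param seed integer seed
#' @return n x 2 coordinate matrix
#' @export
project_2d <- function(X, perplexity = 50, learning_rate = 600,
                       n_iter = 300L, seed = 1L) {
  X <- as_batch(X)
  n <- nrow(X)
  if (n <= 3 * perplexity) stop("perplexity too large for n")
  d2 <- pairwise_sq(X, X)
  # per-point precision by bisection to match the target perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    lo <- 1e-20; hi <- 1e20; beta <- 1
    di <- d2[i, -i]
    for (iter in 1:40) {
      p <- exp(-di * beta)
      sp <- sum(p)
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (hi == 1e20) beta * 2 else (beta + hi) / 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- p / sp
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Yc <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
    for (it in seq_len(n_iter)) {
      num <- 1 / (1 + pairwise_sq(Yc, Yc)); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      mult <- 4 * (P * (if (it < 100) 4 else 1) - Q) * num
      grad <- (diag(rowSums(mult)) - mult) %*% Yc
      mom <- if (it < 250) 0.5 else 0.8
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain <- pmax(gain, 0.01)
      inc <- mom * inc - learning_rate * gain * grad
      Yc <- Yc + inc
      Yc <- sweep(Yc, 2, colMeans(Yc))
    }
    Yc
  })
}
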