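# Six self-supervised pretext transformations with pseudo-labels.
#
# Parameter ranges (defaults): SNR alpha in [2, 45] dB, scale b in [0.1, 10],
# permutation/time-warp segment count m in [2, 40], stretch factor k in
# [1.05, 4]. Signal powers are linear mean-squared amplitudes; their dB
# expression is 10*log10(power), the only convention under which the noise
# power rule 10^((E_dB - alpha)/10) achieves the requested SNR.

transform_kinds <- function() c("noise", "scale", "invert", "permute", "negate", "timewarp")

#' Default pretext parameter ranges
#' @return named list of (lo, hi) ranges for alpha, b, m, k
#' @export
transform_ranges <- function() {
  list(alpha = c(2, 45), b = c(0.1, 10), m = c(2L, 40L), k = c(1.05, 4))
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' Noise variance is \code{10^((E_dB - alpha)/10)} where \code{E_dB} is the
#' signal power in dB; the achieved SNR is therefore \code{alpha} in
#' expectation.
#'
#' @param e numeric signal (not all zero)
#' @param alpha target SNR in dB
#' @param seed optional integer seed
#' @return noisy signal
#' @export
add_noise <- function(e, alpha, seed = NULL) {
  p_sig <- mean(e^2)
  if (p_sig == 0) stop("SNR undefined for an all-zero signal")
  e_db <- 10 * log10(p_sig)
  p_noise <- 10^((e_db - alpha) / 10)
  noise <- if (is.null(seed)) stats::rnorm(length(e), 0, sqrt(p_noise))
           else with_seed(seed, stats::rnorm(length(e), 0, sqrt(p_noise)))
  e + noise
}

#' Scale a signal by a constant positive factor
#' @param e numeric signal
#' @param b scale factor (> 0)
#' @export
scale_signal <- function(e, b) {
  if (b <= 0) stop("scale factor must be positive")
  b * e
}

#' Reverse a signal in time
#' @param e numeric signal
#' @export
time_invert <- function(e) rev(e)

#' Negate a signal (polarity reversal)
#' @param e numeric signal
#' @export
negate_signal <- function(e) -e

# split 1..n into m near-equal contiguous parts (remainder to leading parts)
split_bounds <- function(n, m) {
  base <- n %/% m
  extra <- n %% m
  sizes <- rep(base, m) + c(rep(1L, extra), rep(0L, m - extra))
  ends <- cumsum(sizes)
  cbind(start = c(1L, utils::head(ends, -1L) + 1L), end = ends)
}

#' Randomly permute contiguous signal segments
#'
#' The signal is split into \code{m} near-equal parts which are reordered by
#' a seeded non-identity permutation; the sample multiset is preserved.
#'
#' @param e numeric signal
#' @param m number of parts (2 <= m <= length(e))
#' @param seed integer seed
#' @export
permute_segments <- function(e, m, seed = 1L) {
  m <- as.integer(m)
  if (m < 2 || m > length(e)) stop("m must be in [2, length(e)]")
  b <- split_bounds(length(e), m)
  perm <- with_seed(seed, {
    p <- sample.int(m)
    while (all(p == seq_len(m))) p <- sample.int(m)
    p
  })
  unlist(lapply(perm, function(i) e[b[i, 1]:b[i, 2]]), use.names = FALSE)
}

# linear-interpolation resize of a vector to n_out samples
resize_lin <- function(x, n_out) {
  if (length(x) == 1L) return(rep(x, n_out))
  stats::approx(seq_along(x), x, n = n_out)$y
}

#' Time-warp a signal by stretching and compressing segments
#'
#' The signal is split into \code{m} windows; a seeded random half is
#' stretched by \code{k} (interpolation) and the rest compressed by
#' \code{1/k}; the concatenation is clipped or zero-padded back to the input
#' length.
#'
#' @param e numeric signal
#' @param m number of windows (>= 2)
#' @param k stretch factor (>= 1)
#' @param seed integer seed
#' @export
time_warp <- function(e, m, k, seed = 1L) {
  if (k < 1) stop("stretch factor k must be >= 1")
  m <- as.integer(m)
  stopifnot(m >= 2, m <= length(e))
  b <- split_bounds(length(e), m)
  stretch_set <- with_seed(seed, sample.int(m, m %/% 2L))
  parts <- lapply(seq_len(m), function(i) {
    seg <- e[b[i, 1]:b[i, 2]]
    fac <- if (i %in% stretch_set) k else 1 / k
    resize_lin(seg, max(1L, round(length(seg) * fac)))
  })
  out <- unlist(parts, use.names = FALSE)
  n <- length(e)
  if (length(out) >= n) out[seq_len(n)] else c(out, numeric(n - length(out)))
}

#' Apply one named transformation drawn from the configured ranges
#' @keywords internal
apply_transform <- function(e, kind, ranges = transform_ranges(), seed = 1L) {
  with_seed(seed, {
    switch(kind,
      noise = add_noise(e, stats::runif(1, ranges$alpha[1], ranges$alpha[2])),
      scale = scale_signal(e, stats::runif(1, ranges$b[1], ranges$b[2])),
      invert = time_invert(e),
      permute = permute_segments(e, sample(ranges$m[1]:min(ranges$m[2], length(e)), 1),
                                 seed = seed + 1L),
      negate = negate_signal(e),
      timewarp = time_warp(e, sample(ranges$m[1]:min(ranges$m[2], length(e)), 1),
                           stats::runif(1, ranges$k[1], ranges$k[2]), seed = seed + 1L),
      stop("unknown transformation kind: ", kind))
  })
}

#' Build the pseudo-labeled multi-task pretext dataset
#'
#' Each input segment yields seven examples: the original (all labels
#' negative) plus one copy per transformation with parameters drawn uniformly
#' from \code{ranges}.
#'
#' @param segments list of numeric windows (equal lengths)
#' @param ranges parameter ranges, see \code{\link{transform_ranges}}
#' @param seed integer seed
#' @return list with \code{x} (matrix, one row per example) and \code{labels}
#'   (matrix n x 6 of 0/1, columns named by transformation)
#' @export
build_pretext_dataset <- function(segments, ranges = transform_ranges(), seed = 1L) {
  stopifnot(length(segments) > 0)
  kinds <- transform_kinds()
  wl <- length(segments[[1]])
  n <- length(segments) * 7L
  x <- matrix(0, n, wl)
  labels <- matrix(0L, n, 6L, dimnames = list(NULL, kinds))
  row <- 0L
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    if (length(seg) != wl) stop("segment ", si, " has a different window length")
    row <- row + 1L
    x[row, ] <- seg
    for (ki in seq_along(kinds)) {
      row <- row + 1L
      out <- tryCatch(
        apply_transform(seg, kinds[ki], ranges, seed = seed + si * 101L + ki),
        error = function(err)
          stop("transformation '", kinds[ki], "' failed on segment ", si, ": ",
               conditionMessage(err)))
      x[row, ] <- out
      labels[row, ki] <- 1L
    }
  }
  list(x = x, labels = labels)
}
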