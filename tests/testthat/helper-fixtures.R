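# Shared fixtures, built once per test run and memoized.
#
# All test data is generated in code at a reduced rate (32 Hz, 4 s windows =
# 128 samples) so model-based tests stay fast; signal-level tests that need
# the native rates build their own records.

.fix <- new.env()

fix_cached <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

small_pre_cfg <- function(window_s = 4) {
  preprocess_config(target_fs = 32, ecg_band = c(0.5, 14),
                    ppg_band = c(0.5, 8), window_s = window_s)
}

# clean two-subject cohort preprocessed at 32 Hz
fix_segments <- function() {
  fix_cached("segments", function() {
    coh <- make_cohort(2, 60, seed = 11, artifact_level = 0)
    preprocess_cohort(coh, small_pre_cfg())
  })
}

# reduced generator / critic configurations used across model tests
small_gen_cfg <- function() {
  generator_config(L = 2L, enc_channels = c(8L, 8L), kernel = 9L,
                   d_model = 16L, n_layers = 1L, heads = 2L, dropout = 0,
                   max_tokens = 256L)
}

small_disc_cfg <- function() {
  discriminator_config(conv_kernels = c(17L, 9L, 5L),
                       conv_channels = c(8L, 12L, 16L), d_model = 16L,
                       tokens = 8L, fc_embed = 32L, fc_hidden = 16L,
                       trunk = 16L, dropout = 0)
}

# brute-force discrete Frechet distance by enumeration over all monotone
# couplings (exponential; for n, m <= 5 only) -- independent oracle
frechet_bruteforce <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  walk <- function(i, j, cur) {
    cur <- max(cur, d(i, j))
    if (cur >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- min(best, cur)
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1L, j, cur)
    if (j < m) walk(i, j + 1L, cur)
    if (i < n && j < m) walk(i + 1L, j + 1L, cur)
    invisible(NULL)
  }
  walk(1L, 1L, 0)
  best
}

# match detected peak times against ground truth within a tolerance;
# returns recall, precision
match_peaks <- function(detected, truth, tol) {
  if (!length(truth)) return(c(recall = NA, precision = NA))
  hit <- vapply(truth, function(tt) any(abs(detected - tt) <= tol), logical(1))
  good <- vapply(detected, function(dd) any(abs(truth - dd) <= tol), logical(1))
  c(recall = mean(hit), precision = if (length(detected)) mean(good) else 0)
}
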