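# Preprocessing chain: alignment, cubic-spline resampling, zero-phase
# band-pass filtering, median despiking, overlapped segmentation and
# invertible person-specific min-max normalization to (-1, 1).

#' Preprocessing configuration
#'
#' @param target_fs common sampling rate after resampling, Hz
#' @param ecg_band FIR band-pass edges for ECG, Hz
#' @param ppg_band Butterworth band-pass edges for PPG, Hz
#' @param median_kernel odd running-median width in samples
#' @param window_s segment window length in seconds, one of
#'   4, 8, 16, 32, 64, 96, 128, 160
#' @param overlap_frac fractional overlap between consecutive windows
#' @return a \code{preprocess_config} list
#' @export
preprocess_config <- function(target_fs = 130, ecg_band = c(0.5, 45),
                              ppg_band = c(0.5, 8), median_kernel = 5L,
                              window_s = 4, overlap_frac = 0.2) {
  stopifnot(ecg_band[1] > 0, ecg_band[1] < ecg_band[2],
            ecg_band[2] < target_fs / 2,
            ppg_band[1] > 0, ppg_band[1] < ppg_band[2],
            ppg_band[2] < target_fs / 2,
            median_kernel %% 2 == 1, median_kernel >= 3,
            overlap_frac >= 0, overlap_frac < 1,
            window_s %in% c(4, 8, 16, 32, 64, 96, 128, 160))
  structure(list(target_fs = target_fs, ecg_band = ecg_band,
                 ppg_band = ppg_band, median_kernel = as.integer(median_kernel),
                 window_s = window_s, overlap_frac = overlap_frac),
            class = "preprocess_config")
}

#' Cubic-spline resampling onto a uniform grid
#'
#' @param x numeric signal (>= 4 samples)
#' @param fs_in input sampling rate, Hz
#' @param fs_out output sampling rate, Hz
#' @return resampled signal of length \code{round(duration * fs_out)}
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (length(x) < 4) stop("signal too short to resample (need >= 4 samples)")
  duration <- length(x) / fs_in
  n_out <- round(duration * fs_out)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  # xout may exceed the last input time by under one input sample; the cubic
  # extrapolates that sub-sample tail
  stats::spline(t_in, x, xout = t_out, method = "fmm")$y
}

# zero-phase FIR band-pass (windowed-sinc design, delay-compensated)
#' Band-pass filter an ECG trace (0.5-45 Hz FIR, zero phase)
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param band passband edges, Hz
#' @return filtered signal, same length
#' @export
filter_ecg <- function(x, fs, band = c(0.5, 45)) {
  stopifnot(fs > 2 * band[2])
  x <- x - mean(x)                     # exact DC rejection
  ntaps <- 2L * round(1.5 * fs) + 1L   # odd length, ~1.5 s: narrow transition
  h <- signal::fir1(ntaps - 1L, band / (fs / 2), type = "pass")
  d <- (ntaps - 1L) / 2L
  padded <- c(rep(x[1], d), x, rep(x[length(x)], d))
  y <- stats::filter(padded, h, sides = 1)
  as.numeric(y[(2L * d + 1L):(2L * d + length(x))])
}

#' Band-pass filter a PPG trace (0.5-8 Hz Butterworth, forward-backward)
#' @inheritParams filter_ecg
#' @export
filter_ppg <- function(x, fs, band = c(0.5, 8)) {
  stopifnot(fs > 2 * band[2])
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  pad <- min(length(x) - 1L, 3L * fs)
  padded <- c(rev(x[2:(pad + 1L)]), x, rev(x[(length(x) - pad):(length(x) - 1L)]))
  y <- signal::filtfilt(bf, padded)
  as.numeric(y[(pad + 1L):(pad + length(x))])
}

#' Running-median despiking with edge replication
#'
#' @param x numeric signal
#' @param kernel odd window width in samples (>= 3)
#' @return despiked signal, same length
#' @export
median_despike <- function(x, kernel = 5L) {
  if (kernel %% 2 != 1 || kernel < 3) stop("kernel must be odd and >= 3")
  h <- (kernel - 1L) %/% 2L
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  y <- stats::runmed(padded, kernel, endrule = "keep")
  as.numeric(y[(h + 1L):(h + length(x))])
}

# simple local-maximum peak picker used during alignment
naive_peaks <- function(x, fs, min_dist_s, thresh_q = 0.6) {
  n <- length(x)
  thr <- stats::quantile(x, thresh_q) + 0.3 * (max(x) - stats::quantile(x, thresh_q))
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  if (!length(cand)) return(numeric(0))
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if ((i - last) / fs >= min_dist_s) {
      keep <- c(keep, i); last <- i
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i; last <- i
    }
  }
  (keep - 1) / fs
}

#' Align the PPG channel to the ECG channel of a record
#'
#' Estimates the pulse-arrival lag by scanning candidate shifts of the PPG
#' peak train against the ECG R-peak train and maximizing their
#' cross-correlation at the ECG rate; the PPG is then advanced by that lag
#' (edge padding preserves length).
#'
#' @param record a \code{signal_record} (both channels >= 10 s)
#' @param max_lag_s largest lag scanned, seconds
#' @return the record with aligned \code{ppg} and an \code{alignment_shift_s} field
#' @export
align_pair <- function(record, max_lag_s = 0.6) {
  stopifnot(record$duration >= 10)
  fs_scan <- record$ecg_fs
  ecg_pk <- naive_peaks(record$ecg, record$ecg_fs, 0.25)
  ppg_pk <- naive_peaks(record$ppg, record$ppg_fs, 0.3)
  if (length(ecg_pk) < 3 || length(ppg_pk) < 3)
    stop("no detectable peaks in one of the channels")
  n <- round(record$duration * fs_scan)
  tr_e <- numeric(n); tr_p <- numeric(n)
  tr_e[pmin(n, round(ecg_pk * fs_scan) + 1)] <- 1
  tr_p[pmin(n, round(ppg_pk * fs_scan) + 1)] <- 1
  # widen impulses so near-misses still correlate
  w <- round(0.03 * fs_scan)
  ker <- rep(1, 2 * w + 1)
  tr_e <- stats::filter(tr_e, ker, sides = 2); tr_e[is.na(tr_e)] <- 0
  tr_p <- stats::filter(tr_p, ker, sides = 2); tr_p[is.na(tr_p)] <- 0
  lags <- 0:round(max_lag_s * fs_scan)
  score <- vapply(lags, function(l) {
    if (l == 0) sum(tr_e * tr_p)
    else sum(tr_e[1:(n - l)] * tr_p[(l + 1):n])
  }, numeric(1))
  shift_s <- lags[which.max(score)] / fs_scan
  shift_n <- round(shift_s * record$ppg_fs)
  ppg <- record$ppg
  if (shift_n > 0) {
    ppg <- c(ppg[(shift_n + 1):length(ppg)], rep(ppg[length(ppg)], shift_n))
  }
  record$ppg <- ppg
  record$alignment_shift_s <- shift_s
  record
}

#' Segment two equal-rate channels into overlapped window pairs
#'
#' @param ecg,ppg equal-length numeric signals at \code{fs}
#' @param fs sampling rate, Hz
#' @param window_s window length, seconds
#' @param overlap_frac fractional overlap in [0, 1)
#' @return list of lists with \code{e}, \code{p}, \code{start_time}; trailing
#'   partial windows are dropped
#' @export
segment_pairs <- function(ecg, ppg, fs, window_s, overlap_frac = 0.2) {
  stopifnot(length(ecg) == length(ppg))
  w <- round(window_s * fs)
  if (length(ecg) < w) stop("signal shorter than one window")
  hop <- max(1L, round(w * (1 - overlap_frac)))
  starts <- seq(1L, length(ecg) - w + 1L, by = hop)
  lapply(starts, function(s)
    list(e = ecg[s:(s + w - 1L)], p = ppg[s:(s + w - 1L)],
         start_time = (s - 1L) / fs))
}

#' Fit per-subject min-max normalization parameters
#'
#' @param segments list of segment pairs (fields \code{e}, \code{p})
#' @return \code{norm_params}: per-channel (min, max)
#' @export
fit_norm <- function(segments) {
  e <- range(unlist(lapply(segments, `[[`, "e")))
  p <- range(unlist(lapply(segments, `[[`, "p")))
  if (e[1] == e[2] || p[1] == p[2]) stop("degenerate constant channel")
  structure(list(e_min = e[1], e_max = e[2], p_min = p[1], p_max = p[2]),
            class = "norm_params")
}

norm_channel <- function(x, lo, hi) {
  y <- 2 * (x - lo) / (hi - lo) - 1
  clipped <- sum(y > 1 | y < -1)
  if (clipped > 0)
    warning(sprintf("%d samples outside fitted range clipped to [-1, 1]", clipped),
            call. = FALSE)
  pmin(1, pmax(-1, y))
}

#' Apply / invert person-specific min-max normalization
#'
#' \code{normalize_window} maps the fitted subject minimum to -1 and maximum
#' to +1; values beyond the fitted range (e.g. unseen test windows) are
#' clipped with a warning. \code{denormalize_window} inverts the affine map.
#'
#' @param seg a segment pair (fields \code{e}, \code{p}) or numeric vector
#' @param np fitted \code{norm_params}
#' @param channel for numeric input, which channel's parameters to use
#' @return the transformed segment / vector
#' @export
normalize_window <- function(seg, np, channel = c("e", "p")) {
  if (is.numeric(seg)) {
    channel <- match.arg(channel)
    return(if (channel == "e") norm_channel(seg, np$e_min, np$e_max)
           else norm_channel(seg, np$p_min, np$p_max))
  }
  seg$e <- norm_channel(seg$e, np$e_min, np$e_max)
  seg$p <- norm_channel(seg$p, np$p_min, np$p_max)
  seg
}

#' @rdname normalize_window
#' @export
denormalize_window <- function(seg, np, channel = c("e", "p")) {
  inv <- function(y, lo, hi) (y + 1) / 2 * (hi - lo) + lo
  if (is.numeric(seg)) {
    channel <- match.arg(channel)
    return(if (channel == "e") inv(seg, np$e_min, np$e_max)
           else inv(seg, np$p_min, np$p_max))
  }
  seg$e <- inv(seg$e, np$e_min, np$e_max)
  seg$p <- inv(seg$p, np$p_min, np$p_max)
  seg
}

#' Run the full preprocessing chain on one record
#'
#' Order: align, resample both channels to \code{target_fs}, band-pass filter
#' (FIR for ECG, Butterworth for PPG, both zero phase), median despike,
#' segment with overlap, then person-specific min-max normalization.
#'
#' @param record a \code{signal_record}
#' @param cfg a \code{\link{preprocess_config}}
#' @param align whether to run peak-train alignment first
#' @return list with \code{segments} (normalized pairs carrying
#'   \code{subject_id}), \code{norm_params}, \code{alignment_shift_s}
#' @export
preprocess_record <- function(record, cfg = preprocess_config(), align = TRUE) {
  if (align) record <- align_pair(record)
  fs <- cfg$target_fs
  ecg <- resample_signal(record$ecg, record$ecg_fs, fs)
  ppg <- resample_signal(record$ppg, record$ppg_fs, fs)
  n <- min(length(ecg), length(ppg))
  ecg <- ecg[seq_len(n)]; ppg <- ppg[seq_len(n)]
  ecg <- median_despike(filter_ecg(ecg, fs, cfg$ecg_band), cfg$median_kernel)
  ppg <- median_despike(filter_ppg(ppg, fs, cfg$ppg_band), cfg$median_kernel)
  raw <- segment_pairs(ecg, ppg, fs, cfg$window_s, cfg$overlap_frac)
  np <- fit_norm(raw)
  segs <- lapply(raw, function(s) {
    s <- normalize_window(s, np)
    s$subject_id <- record$subject_id
    s$fs <- fs
    s$window_s <- cfg$window_s
    s
  })
  list(segments = segs, norm_params = np,
       alignment_shift_s = record$alignment_shift_s)
}

#' Preprocess a whole cohort
#'
#' @param cohort list of \code{signal_record}
#' @param cfg a \code{\link{preprocess_config}}
#' @param align whether to run alignment
#' @return list with pooled \code{segments} and per-subject \code{norm_params}
#' @export
preprocess_cohort <- function(cohort, cfg = preprocess_config(), align = TRUE) {
  per <- lapply(cohort, preprocess_record, cfg = cfg, align = align)
  segs <- do.call(c, lapply(per, `[[`, "segments"))
  np <- lapply(per, `[[`, "norm_params")
  names(np) <- vapply(cohort, `[[`, character(1), "subject_id")
  list(segments = segs, norm_params = np)
}
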