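# Evaluation battery: RMSE, discrete Frechet distance, Pearson correlation,
# and heart-rate MAE built on Pan-Tompkins R-peak detection and
# slope-sum/adaptive-threshold systolic-peak detection.

#' Root-mean-square error between two equal-length signals
#'
#' Computed on denormalized (original-scale, mV) signals when used for
#' reporting.
#'
#' @param y,yr numeric vectors of equal length
#' @return scalar RMSE
#' @export
rmse <- function(y, yr) {
  if (length(y) != length(yr)) stop("length mismatch")
  sqrt(mean((y - yr)^2))
}

#' Discrete Frechet distance between two curves
#'
#' Curves are (t, y) polylines; by default the x-coordinate is the sample
#' index. Computed by the standard coupling dynamic program (compiled).
#'
#' @param y,yr numeric vectors (possibly different lengths)
#' @param tx,ty x-coordinates for each curve (defaults: sample indices)
#' @return scalar distance (>= 0, 0 iff identical curves)
#' @export
frechet_distance <- function(y, yr, tx = seq_along(y), ty = seq_along(yr)) {
  if (!length(y) || !length(yr)) stop("empty input")
  frechet_dp(cbind(tx, y), cbind(ty, yr))
}

#' Pearson correlation between two signals
#'
#' @param y,yr numeric vectors of equal length, neither constant
#' @return correlation in [-1, 1]
#' @export
pearson_r <- function(y, yr) {
  if (length(y) != length(yr)) stop("length mismatch")
  if (stats::sd(y) == 0 || stats::sd(yr) == 0) stop("zero-variance input")
  cy <- y - mean(y); cr <- yr - mean(yr)
  sum(cy * cr) / (sqrt(sum(cy^2)) * sqrt(sum(cr^2)))
}

# local maxima above a threshold with a minimum spacing (keeps the larger
# of two close candidates)
local_maxima <- function(x, min_dist, thr = -Inf) {
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] > x[cand + 1]]
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || i - keep[length(keep)] >= min_dist) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  keep
}

#' Pan-Tompkins R-peak detection
#'
#' Band-pass (5-15 Hz) -> derivative -> squaring -> moving-window integration
#' (150 ms) -> adaptive signal/noise thresholding with a 200 ms refractory
#' period. Detected events are snapped to the maximum of the squared
#' band-passed signal, making the result polarity-invariant and sample-exact
#' on clean recordings.
#'
#' @param ecg numeric ECG trace (>= 4 s)
#' @param fs sampling rate, Hz
#' @return R-peak times in seconds (strictly increasing, min spacing 200 ms)
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 4 * fs) stop("need at least 4 s of signal")
  if (stats::sd(ecg) == 0) stop("flat input")
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, ecg))
  sq <- c(0, diff(filt))^2
  w <- max(3L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  refractory <- max(1L, round(0.2 * fs))
  cand <- local_maxima(mwi, refractory)
  if (!length(cand)) stop("no QRS candidates found")
  # adaptive signal/noise levels (Pan-Tompkins running estimates)
  spki <- max(mwi[seq_len(min(length(mwi), 2L * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(length(mwi), 2L * fs))]) * 0.5
  peaks <- integer(0)
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] > thr) {
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (!length(peaks)) stop("no peaks above the adaptive threshold")
  # snap each event to the local maximum of the squared band-passed signal
  half <- round(0.1 * fs)
  fsq <- filt^2
  snapped <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(fsq), i + half)
    as.integer(lo + which.max(fsq[lo:hi]) - 1L)
  }, integer(1))
  snapped <- sort(unique(snapped))
  # enforce the refractory spacing after snapping
  out <- snapped[c(TRUE, diff(snapped) >= refractory)]
  (out - 1) / fs
}

#' Systolic-peak detection for PPG
#'
#' Band-passes the signal (0.5-8 Hz), builds a clipped slope-sum function,
#' thresholds it adaptively into beat events (minimum spacing 250 ms), then
#' snaps each event to the local maximum of the raw signal.
#'
#' @param ppg numeric PPG trace (>= 4 s)
#' @param fs sampling rate, Hz
#' @return systolic-peak times in seconds
#' @export
detect_ppg_peaks <- function(ppg, fs) {
  if (length(ppg) < 4 * fs) stop("need at least 4 s of signal")
  if (stats::sd(ppg) == 0) stop("flat input")
  filt <- filter_ppg(ppg, fs)
  # slope-sum function over a 128 ms window (positive slopes only)
  slope <- pmax(c(0, diff(filt)), 0)
  w <- max(2L, round(0.128 * fs))
  ssf <- as.numeric(stats::filter(slope, rep(1, w), sides = 1))
  ssf[is.na(ssf)] <- 0
  min_dist <- max(1L, round(0.25 * fs))
  thr <- 0.4 * stats::quantile(ssf[ssf > 0], 0.9)
  events <- local_maxima(ssf, min_dist, thr)
  if (!length(events)) stop("no systolic candidates found")
  half <- round(0.2 * fs)
  snapped <- vapply(events, function(i) {
    lo <- max(1L, i - half); hi <- min(length(ppg), i + half)
    as.integer(lo + which.max(ppg[lo:hi]) - 1L)
  }, integer(1))
  snapped <- sort(unique(snapped))
  out <- snapped[c(TRUE, diff(snapped) >= min_dist)]
  (out - 1) / fs
}

#' Heart-rate mean absolute error across segments
#'
#' Per segment the heart rate is 60 / mean(RR); segments with fewer than two
#' peaks in either train are excluded and counted.
#'
#' @param peaks_gt,peaks_q lists of per-segment peak-time vectors (seconds)
#' @return list: \code{mae} (bpm), \code{n} retained segments,
#'   \code{excluded} count, \code{hr_gt}, \code{hr_q} per retained segment
#' @export
mae_hr <- function(peaks_gt, peaks_q) {
  stopifnot(length(peaks_gt) == length(peaks_q))
  hr <- function(p) if (length(p) >= 2) 60 / mean(diff(p)) else NA_real_
  hg <- vapply(peaks_gt, hr, numeric(1))
  hq <- vapply(peaks_q, hr, numeric(1))
  ok <- !is.na(hg) & !is.na(hq)
  if (!any(ok)) stop("zero retained segments")
  list(mae = mean(abs(hg[ok] - hq[ok])), n = sum(ok), excluded = sum(!ok),
       hr_gt = hg[ok], hr_q = hq[ok])
}

#' Per-segment metric battery for a generator on preprocessed pairs
#'
#' Applies \code{gen_fn} to each normalized PPG window, denormalizes both the
#' generated and the reference ECG to mV, and computes RMSE, discrete Frechet
#' distance, Pearson correlation, and the three heart rates (ground-truth
#' ECG, generated ECG, input PPG). Degenerate windows (zero variance) are
#' flagged, not dropped silently.
#'
#' @param segments list of normalized segment pairs carrying subject ids
#' @param gen_fn function mapping a normalized PPG window to a normalized ECG
#'   window (e.g. a trained generator, or an oracle)
#' @param norm_params named list of per-subject \code{norm_params}
#' @param fs sampling rate of the segments, Hz
#' @return data.frame with one row per segment: rmse, fd, rho, hr flags and
#'   peak counts; peak trains attached as attributes \code{peaks_*}
#' @export
evaluate_segments <- function(segments, gen_fn, norm_params, fs) {
  pk_gt <- list(); pk_gen <- list(); pk_ppg <- list()
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    np <- norm_params[[seg$subject_id]]
    # oracles (e.g. identity-on-clean-ECG) may take the whole segment too
    gen_n <- if (length(formals(gen_fn)) >= 2) gen_fn(seg$p, seg) else gen_fn(seg$p)
    e_mV <- denormalize_window(seg$e, np, "e")
    g_mV <- denormalize_window(gen_n, np, "e")
    p_raw <- denormalize_window(seg$p, np, "p")
    degenerate <- stats::sd(g_mV) == 0 || stats::sd(e_mV) == 0
    pg <- tryCatch(detect_r_peaks(e_mV, fs), error = function(e) numeric(0))
    pq <- tryCatch(detect_r_peaks(g_mV, fs), error = function(e) numeric(0))
    pp <- tryCatch(detect_ppg_peaks(p_raw, fs), error = function(e) numeric(0))
    pk_gt[[i]] <<- pg; pk_gen[[i]] <<- pq; pk_ppg[[i]] <<- pp
    data.frame(
      segment = i, subject_id = seg$subject_id,
      rmse = rmse(e_mV, g_mV),
      fd = frechet_distance(e_mV, g_mV),
      rho = if (degenerate) NA_real_ else pearson_r(e_mV, g_mV),
      degenerate = degenerate,
      n_peaks_gt = length(pg), n_peaks_gen = length(pq),
      n_peaks_ppg = length(pp))
  })
  out <- do.call(rbind, rows)
  attr(out, "peaks_gt") <- pk_gt
  attr(out, "peaks_gen") <- pk_gen
  attr(out, "peaks_ppg") <- pk_ppg
  out
}

#' Aggregate report over window lengths
#'
#' Re-segments a cohort at each window length, runs \code{gen_fn} on held-out
#' windows and aggregates mean and SD of RMSE, FD, rho and the two
#' heart-rate MAEs (generated ECG vs ground truth, and input PPG vs ground
#' truth).
#'
#' @param cohort list of \code{signal_record}
#' @param gen_fn normalized-window generator function
#' @param window_lengths seconds, subset of 4, 8, 16, 32, 64, 96, 128, 160
#' @param cfg base \code{\link{preprocess_config}}
#' @param align run alignment during preprocessing
#' @return data.frame shaped like the report tables: one row per window length
#' @export
evaluate_windows <- function(cohort, gen_fn, window_lengths = c(4, 8),
                             cfg = preprocess_config(), align = TRUE) {
  rows <- lapply(window_lengths, function(ws) {
    cfg$window_s <- ws
    pp <- preprocess_cohort(cohort, cfg, align = align)
    per <- evaluate_segments(pp$segments, gen_fn, pp$norm_params, cfg$target_fs)
    mh_e <- mae_hr(attr(per, "peaks_gt"), attr(per, "peaks_gen"))
    mh_p <- mae_hr(attr(per, "peaks_gt"), attr(per, "peaks_ppg"))
    data.frame(
      segment_length_s = ws, n_segments = nrow(per),
      rmse_mean = mean(per$rmse), rmse_sd = stats::sd(per$rmse),
      fd_mean = mean(per$fd), fd_sd = stats::sd(per$fd),
      rho_mean = mean(per$rho, na.rm = TRUE),
      rho_sd = stats::sd(per$rho, na.rm = TRUE),
      mae_e_mean = mh_e$mae, mae_p_mean = mh_p$mae,
      n_flagged = sum(per$degenerate))
  })
  do.call(rbind, rows)
}
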