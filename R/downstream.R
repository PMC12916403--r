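# Atrial-fibrillation downstream harness: baseline isolation by QRS excision,
# Welch band power, synthetic AF cohorts, the real/generated data-mixing
# experiment and per-class baseline comparison.

#' Excise QRS complexes and interpolate the baseline
#'
#' Removes samples within +/- \code{widen_ms} of each detected R peak and
#' bridges the gaps linearly, isolating the baseline (P/T regions and
#' wander) from QRS energy.
#'
#' @param ecg numeric ECG trace
#' @param fs sampling rate, Hz
#' @param widen_ms half-width removed around each R peak, milliseconds
#' @param r_peaks optional known R-peak times (seconds); detected when NULL
#' @return numeric baseline trace, same length as the input
#' @export
excise_qrs <- function(ecg, fs, widen_ms = 60, r_peaks = NULL) {
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(ecg, fs)
  if (!length(r_peaks)) stop("no R peaks found")
  n <- length(ecg)
  half <- round(widen_ms / 1000 * fs)
  drop <- unique(unlist(lapply(round(r_peaks * fs) + 1, function(i)
    max(1L, i - half):min(n, i + half))))
  keep <- setdiff(seq_len(n), drop)
  if (length(keep) < 2) stop("QRS excision removed the whole trace")
  as.numeric(stats::approx(keep, ecg[keep], xout = seq_len(n), rule = 2)$y)
}

#' Welch periodogram band power
#'
#' Hann-windowed segment-averaged periodogram integrated over \code{band} by
#' the trapezoid rule.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param band two-element frequency band, Hz (within Nyquist)
#' @param window_s Welch segment length, seconds (default 8; use >= 20 to
#'   resolve the 0.05 Hz band edge)
#' @param overlap segment overlap fraction
#' @return band power in squared signal units
#' @export
welch_band_power <- function(x, fs, band, window_s = 8, overlap = 0.5) {
  stopifnot(band[1] >= 0, band[2] > band[1], band[2] <= fs / 2)
  nw <- round(window_s * fs)
  if (length(x) < nw) stop("signal shorter than one Welch window")
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  if (length(starts) < 1) stop("signal too short")
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))  # Hann
  u <- sum(win^2)
  nf <- nw %/% 2 + 1
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)] * win
    sp <- abs(stats::fft(seg))^2 / (u * fs)
    half <- sp[seq_len(nf)]
    # one-sided: double all bins except DC (and Nyquist when nw is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nw %% 2 == 0) dbl[nf] <- 1
    psd <- psd + half * dbl
  }
  psd <- psd / length(starts)
  f <- (seq_len(nf) - 1) * fs / nw
  sel <- f >= band[1] & f <= band[2]
  if (sum(sel) < 2) return(sum(psd[sel]) * fs / nw)
  sum(diff(f[sel]) * (utils::head(psd[sel], -1) + utils::tail(psd[sel], -1)) / 2)
}

#' Synthetic AF-like cohort for desk-scale testing
#'
#' AF hallmarks are emulated as highly irregular RR intervals, absent
#' P waves, and a 4-9 Hz fibrillatory baseline oscillation; non-AF subjects
#' are ordinary sinus-rhythm records. Labels are returned alongside.
#'
#' @param n_af,n_normal subject counts
#' @param duration per-subject seconds
#' @param fs ECG sampling rate, Hz
#' @param seed integer seed
#' @return list of records, each with \code{ecg}, \code{ppg},
#'   \code{subject_id}, \code{af} (0/1), \code{r_peak_times}
#' @export
make_af_cohort <- function(n_af, n_normal, duration = 60, fs = 130, seed = 1L) {
  build <- function(i, af) {
    sd0 <- seed * 1000L + i + af * 500L
    with_seed(sd0, {
      hr <- stats::runif(1, 60, 110)
      amps <- c(P = if (af) 0 else stats::runif(1, 0.10, 0.2),
                R = stats::runif(1, 0.8, 1.4),
                T = stats::runif(1, 0.2, 0.4))
      hrv <- if (af) stats::runif(1, 0.12, 0.20) else stats::runif(1, 0.01, 0.04)
      prof <- subject_profile(sprintf("%s%03d", if (af) "AF" else "NSR", i),
                              mean_hr = hr, hrv_sd = hrv,
                              ecg_amplitudes = amps, ppg_lag = 0.25,
                              artifact_level = 0, seed = sd0 + 1L)
      ecg <- generate_ecg(prof, duration, fs)
      sig <- ecg$samples
      if (af) {
        t <- (seq_along(sig) - 1) / fs
        fib_f <- stats::runif(1, 4, 9)
        sig <- sig + 0.06 * sin(2 * pi * fib_f * t + stats::runif(1, 0, 2 * pi)) +
          0.03 * sin(2 * pi * 0.3 * t)
      }
      ppg <- generate_ppg_from_ecg(ecg$r_peaks, duration, fs, lag = 0.25)
      list(subject_id = prof$subject_id, ecg = sig, ppg = ppg, fs = fs,
           af = af, r_peak_times = ecg$r_peaks, duration = duration)
    })
  }
  c(lapply(seq_len(n_af), build, af = 1L),
    lapply(seq_len(n_normal), build, af = 0L))
}

# min-max normalize a window to (-1, 1) by its own range
minmax_unit <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

# cut labeled windows from AF records, optionally resampled to fs_out so
# recurrent classifiers see short sequences during desk-scale runs
af_segments <- function(records, window_s, fs, fs_out = fs) {
  out <- list()
  for (rec in records) {
    sig <- rec$ecg
    if (fs_out != fs) sig <- resample_signal(sig, fs, fs_out)
    w <- round(window_s * fs_out)
    starts <- seq(1L, length(sig) - w + 1L, by = w)
    for (s in starts) {
      out[[length(out) + 1L]] <- list(
        x = minmax_unit(sig[s:(s + w - 1L)]),
        y = rec$af, subject_id = rec$subject_id)
    }
  }
  out
}

#' Train and evaluate an AF classifier under a real/generated mixing protocol
#'
#' Keeps the total training size constant while replacing a
#' \code{1 - real_fraction} share of real segments with generated ones, then
#' trains the chosen classifier and reports accuracy, precision, recall, F1
#' and the confusion matrix on the real test set.
#'
#' @param real_train,gen_train lists of labeled segments (fields \code{x},
#'   \code{y}); generated segments must mirror the real ones' labels
#' @param test list of labeled real test segments (subject-disjoint)
#' @param real_fraction one of 1, 0.75, 0.5, 0.25, 0
#' @param classifier \code{"bidlstm"} or \code{"cnnlstm"}
#' @param epochs,lr,batch training settings
#' @param hidden,fc classifier sizes (reduce for desk-scale runs)
#' @param seed integer seed
#' @return one-row data.frame with the metrics plus a \code{confusion}
#'   attribute (2 x 2 matrix)
#' @export
run_mix_experiment <- function(real_train, gen_train, test,
                               real_fraction = 1.0,
                               classifier = c("bidlstm", "cnnlstm"),
                               epochs = 5L, lr = 5e-3, batch = 16L,
                               hidden = 8L, fc = 16L, seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(real_fraction %in% c(1, 0.75, 0.5, 0.25, 0),
            length(real_train) == length(gen_train))
  n <- length(real_train)
  n_real <- round(real_fraction * n)
  pick <- with_seed(seed, sample.int(n))
  mixed <- c(real_train[pick[seq_len(n_real)]],
             gen_train[pick[-seq_len(n_real)]])
  stopifnot(length(mixed) == n)
  ylab <- vapply(mixed, `[[`, numeric(1), "y")
  if (length(unique(ylab)) < 2) stop("a class is absent from the mixed training set")
  X <- do.call(rbind, lapply(mixed, `[[`, "x"))
  model <- if (classifier == "bidlstm") bidlstm_init(hidden, fc, 0.5, seed)
           else cnnlstm_init(hidden, fc, filters = 4L, dropout = 0.5, seed = seed)
  opt <- adam_init(model$params, lr = lr, beta1 = 0.9, beta2 = 0.999)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      for (b0 in seq(1L, nrow(X), by = batch)) {
        idx <- ord[b0:min(b0 + batch - 1L, nrow(X))]
        fw <- classifier_forward(X[idx, , drop = FALSE], model, train = FALSE)
        p <- fw$prob
        yb <- ad_const(matrix(ylab[idx], ncol = 1L))
        # numerically safe cross-entropy on probabilities
        eps <- 1e-7
        ll <- ad_add(
          ad_mul(yb, ad_neg(ad_log_safe(p, eps))),
          ad_mul(ad_sadd(ad_neg(yb), 1),
                 ad_neg(ad_log_safe(ad_sadd(ad_neg(p), 1), eps))))
        loss <- ad_mean(ll)
        zero_grads(model$params)
        ad_backward(loss, model$params)
        opt <- adam_step(opt)
      }
    }
  })
  Xt <- do.call(rbind, lapply(test, `[[`, "x"))
  yt <- vapply(test, `[[`, numeric(1), "y")
  pt <- classifier_forward(Xt, model, train = FALSE)$prob$v[, 1L]
  pred <- as.integer(pt >= 0.5)
  cm <- matrix(c(sum(pred == 0 & yt == 0), sum(pred == 1 & yt == 0),
                 sum(pred == 0 & yt == 1), sum(pred == 1 & yt == 1)),
               2, 2, dimnames = list(pred = c("0", "1"), truth = c("0", "1")))
  tp <- cm["1", "1"]; fp <- cm["1", "0"]; fn <- cm["0", "1"]
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  out <- data.frame(real_fraction = real_fraction, classifier = classifier,
                    n_train = n, n_test = length(test),
                    accuracy = mean(pred == yt), precision = prec,
                    recall = rec, f1 = f1)
  attr(out, "confusion") <- cm
  out
}

# log with clamping away from zero (composed op: log(x) via exp inverse)
ad_log_safe <- function(x, eps = 1e-7) {
  xv <- pmax(x$v, eps)
  clamped <- ad_cadd(x, pmax(eps - x$v, 0))  # max(x, eps), constant shift a.e.
  ad_node(log(xv), list(clamped),
          function(g, out) list(ad_mul(g, ad_recip(clamped))),
          clamped$req, "log")
}

#' Per-class baseline comparison between real and generated ECG
#'
#' For each paired recording, excises QRS from both traces, then reports the
#' per-class mean and SD of baseline RMSE, discrete Frechet distance, Pearson
#' correlation, and the absolute difference in 0.05-9 Hz Welch band power.
#'
#' @param real_ecgs,gen_ecgs lists of equal length; elements are lists with
#'   \code{ecg}, \code{fs}, \code{af} (class label), optionally \code{r_peak_times}
#' @param widen_ms QRS excision half-width
#' @return data.frame with one row per class
#' @export
baseline_compare <- function(real_ecgs, gen_ecgs, widen_ms = 60) {
  stopifnot(length(real_ecgs) == length(gen_ecgs))
  per <- lapply(seq_along(real_ecgs), function(i) {
    r <- real_ecgs[[i]]; g <- gen_ecgs[[i]]
    stopifnot(length(r$ecg) == length(g$ecg))
    rb <- excise_qrs(r$ecg, r$fs, widen_ms, r$r_peak_times)
    gb <- excise_qrs(g$ecg, g$fs, widen_ms, g$r_peak_times)
    bp <- function(x, fs) welch_band_power(x, fs, c(0.05, 9))
    data.frame(af = r$af, rmse = rmse(rb, gb),
               fd = frechet_distance(rb, gb),
               rho = pearson_r(rb, gb),
               dpow = abs(bp(rb, r$fs) - bp(gb, g$fs)))
  })
  per <- do.call(rbind, per)
  agg <- lapply(split(per, per$af), function(d)
    data.frame(class = if (d$af[1] == 1) "AF" else "non-AF", n = nrow(d),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               fd_mean = mean(d$fd), fd_sd = stats::sd(d$fd),
               rho_mean = mean(d$rho), rho_sd = stats::sd(d$rho),
               dpow_mean = mean(d$dpow), dpow_sd = stats::sd(d$dpow)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
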