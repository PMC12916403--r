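# Synthetic paired PPG/ECG cohort generator.
#
# ECG morphology is a sum of Gaussian bumps per beat (P, Q, R, S, T at fixed
# phase offsets relative to the R peak), which anchors the R maximum exactly
# and yields a known QRS-free component for baseline analysis. PPG pulses use
# a gamma-like asymmetric kernel whose maximum sits at the R peak plus the
# pulse-arrival lag, with a scaled delayed copy as the dicrotic notch.
# RR intervals are i.i.d. truncated normal draws (mean 60/HR, SD = hrv_sd).

#' Create a synthetic subject profile
#'
#' @param subject_id character id
#' @param mean_hr mean heart rate in beats per minute, in [30, 220]
#' @param hrv_sd standard deviation of RR intervals in seconds (>= 0)
#' @param ecg_amplitudes numeric triple: P, R, T wave peak heights in mV
#' @param ppg_lag pulse-arrival delay of the systolic peak after the R peak, seconds
#' @param artifact_level motion-artifact severity in [0, 1]
#' @param seed integer RNG seed; identical profile + seed gives bit-identical signals
#' @return object of class \code{subject_profile}
#' @export
subject_profile <- function(subject_id = "S1", mean_hr = 70, hrv_sd = 0.03,
                            ecg_amplitudes = c(P = 0.15, R = 1.0, T = 0.3),
                            ppg_lag = 0.25, artifact_level = 0, seed = 1L) {
  stopifnot(mean_hr >= 30, mean_hr <= 220, hrv_sd >= 0, ppg_lag >= 0,
            artifact_level >= 0, artifact_level <= 1, length(ecg_amplitudes) == 3)
  structure(list(subject_id = as.character(subject_id), mean_hr = mean_hr,
                 hrv_sd = hrv_sd, ecg_amplitudes = ecg_amplitudes,
                 ppg_lag = ppg_lag, artifact_level = artifact_level,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

# truncated-normal RR draws covering a little more than `duration`
draw_rr <- function(mean_rr, sd_rr, duration) {
  lo <- max(0.25, 0.3 * mean_rr)
  rr <- numeric(0)
  total <- 0
  while (total < duration + 2 * mean_rr) {
    n <- max(8L, ceiling((duration + 2 * mean_rr - total) / mean_rr) + 4L)
    x <- stats::rnorm(n, mean_rr, sd_rr)
    x <- x[x >= lo]
    rr <- c(rr, x)
    total <- sum(rr)
  }
  rr
}

# Gaussian bump helper evaluated on a time grid
gauss_bump <- function(t, center, amp, width) amp * exp(-((t - center)^2) / (2 * width^2))

# per-beat wave description; widths in seconds, offsets relative to the R peak
ecg_wave_spec <- function(amps) {
  list(
    P = list(off = -0.20, amp = amps[[1]], w = 0.025),
    Q = list(off = -0.035, amp = -0.12 * amps[[2]], w = 0.010),
    R = list(off = 0.0, amp = amps[[2]], w = 0.012),
    S = list(off = 0.035, amp = -0.20 * amps[[2]], w = 0.012),
    T = list(off = 0.30, amp = amps[[3]], w = 0.060)
  )
}

# render waves (optionally excluding QRS) for known R-peak times
render_ecg_waves <- function(r_peaks, t, amps, waves = c("P", "Q", "R", "S", "T")) {
  spec <- ecg_wave_spec(amps)
  sig <- numeric(length(t))
  for (rp in r_peaks) {
    for (wn in waves) {
      w <- spec[[wn]]
      lo <- rp + w$off - 6 * w$w; hi <- rp + w$off + 6 * w$w
      i <- which(t >= lo & t <= hi)
      if (length(i)) sig[i] <- sig[i] + gauss_bump(t[i], rp + w$off, w$amp, w$w)
    }
  }
  sig
}

#' Generate a synthetic ECG trace with ground-truth R peaks
#'
#' One P-QRS-T complex per beat; RR intervals are truncated-normal with mean
#' \code{60/mean_hr} and SD \code{hrv_sd}. The returned R-peak times are the
#' exact continuous-time wave maxima.
#'
#' @param profile a \code{\link{subject_profile}}
#' @param duration length of the trace in seconds (> 0)
#' @param fs sampling rate in Hz (>= 100)
#' @return list with \code{samples} (mV) and \code{r_peaks} (seconds)
#' @export
generate_ecg <- function(profile, duration, fs = 130) {
  stopifnot(duration > 0, fs >= 100)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(profile$seed, {
    rr <- draw_rr(60 / profile$mean_hr, profile$hrv_sd, duration)
    r_peaks <- cumsum(rr)
    r_peaks <- r_peaks[r_peaks < duration - 0.05]
    samples <- render_ecg_waves(r_peaks, t, profile$ecg_amplitudes)
    list(samples = samples, r_peaks = r_peaks)
  })
}

# asymmetric pulse kernel with maximum exactly at u = 0 (u measured from the
# systolic-peak time); gamma-like rise, exponential decay
ppg_kernel <- function(u, rise = 0.09, decay = 0.18) {
  k <- numeric(length(u))
  pre <- u <= 0
  k[pre] <- exp(-(u[pre] / rise)^2 / 2)
  k[!pre] <- exp(-u[!pre] / decay)
  k
}

#' Synthesize a PPG trace aligned to given R peaks
#'
#' Each beat contributes one pulse whose systolic maximum lies at
#' \code{r_peak + lag}, plus an optional dicrotic bump.
#'
#' @param r_peaks R-peak times in seconds (non-empty, increasing)
#' @param duration trace length in seconds
#' @param fs sampling rate in Hz
#' @param lag pulse-arrival delay in seconds (>= 0)
#' @param notch_depth relative amplitude of the dicrotic bump in [0, 1)
#' @return numeric vector of PPG samples (arbitrary units, positive baseline)
#' @export
generate_ppg_from_ecg <- function(r_peaks, duration, fs = 64, lag = 0.25,
                                  notch_depth = 0.25) {
  stopifnot(length(r_peaks) > 0, !is.unsorted(r_peaks, strictly = TRUE), lag >= 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  for (rp in r_peaks) {
    peak_t <- rp + lag
    i <- which(t >= peak_t - 0.45 & t <= peak_t + 0.55)
    if (!length(i)) next
    u <- t[i] - peak_t
    sig[i] <- sig[i] + ppg_kernel(u)
    if (notch_depth > 0) {
      # dicrotic bump: delayed, attenuated, narrower copy
      un <- u - 0.25
      sig[i] <- sig[i] + notch_depth * exp(-(un / 0.05)^2 / 2)
    }
  }
  sig + 0.05
}

#' Inject motion artifacts into a signal
#'
#' Adds band-limited random-walk baseline drift, sparse transient spikes, and
#' slow amplitude modulation, all scaled by \code{level}. \code{level = 0}
#' returns the input unchanged.
#'
#' @param signal numeric vector
#' @param fs sampling rate in Hz
#' @param level severity in [0, 1]
#' @param seed integer RNG seed
#' @return corrupted signal, same length
#' @export
add_motion_artifacts <- function(signal, fs, level, seed = 1L) {
  stopifnot(level >= 0, level <= 1)
  if (level == 0) return(signal)
  n <- length(signal)
  amp <- stats::sd(signal)
  if (amp == 0) amp <- 1
  with_seed(seed, {
    # 0.1-1 Hz drift: smoothed random walk
    walk <- cumsum(stats::rnorm(n))
    k <- max(3L, round(fs / 1.0))
    drift <- stats::filter(walk, rep(1 / k, k), sides = 2)
    drift[is.na(drift)] <- 0
    drift <- drift - mean(drift)
    drift <- drift / max(stats::sd(drift), 1e-12)
    # Poisson transient spikes (~0.2 per second at level 1)
    spikes <- numeric(n)
    nsp <- stats::rpois(1, 0.2 * level * n / fs)
    if (nsp > 0) {
      at <- sample.int(n, min(nsp, n))
      spikes[at] <- stats::rnorm(length(at), 0, 4)
    }
    # slow amplitude modulation around 0.15 Hz
    ph <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1) / fs
    am <- 1 + 0.5 * level * sin(2 * pi * 0.15 * t + ph)
    as.numeric(signal * am + level * amp * (1.5 * drift + spikes))
  })
}

#' Generate a cohort of paired PPG/ECG recordings
#'
#' Subject profiles (heart rate, HRV, amplitudes, lag, artifact level) are
#' drawn from physiologic ranges; ECG is sampled at \code{ecg_fs} and PPG at
#' \code{ppg_fs} with ground-truth R peaks retained.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param duration per-subject recording length in seconds
#' @param seed integer RNG seed
#' @param ecg_fs ECG sampling rate in Hz (default 130)
#' @param ppg_fs PPG sampling rate in Hz (default 64)
#' @param artifact_level either NULL (drawn uniformly in [0, 0.3]) or a fixed level
#' @return list of \code{signal_record} objects
#' @export
make_cohort <- function(n_subjects, duration = 120, seed = 1L,
                        ecg_fs = 130, ppg_fs = 64, artifact_level = NULL) {
  stopifnot(n_subjects >= 1)
  profiles <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      subject_profile(
        subject_id = sprintf("S%03d", i),
        mean_hr = stats::runif(1, 55, 95),
        hrv_sd = stats::runif(1, 0.01, 0.06),
        ecg_amplitudes = c(P = stats::runif(1, 0.10, 0.20),
                           R = stats::runif(1, 0.8, 1.4),
                           T = stats::runif(1, 0.2, 0.4)),
        ppg_lag = stats::runif(1, 0.15, 0.35),
        artifact_level = if (is.null(artifact_level))
          stats::runif(1, 0, 0.3) else artifact_level,
        seed = seed * 1000L + i
      )
    })
  })
  lapply(profiles, function(pr) simulate_record(pr, duration, ecg_fs, ppg_fs))
}

#' Simulate one subject's paired recording from a profile
#'
#' @inheritParams make_cohort
#' @param profile a \code{\link{subject_profile}}
#' @return a \code{signal_record}: subject_id, ecg, ecg_fs, ppg, ppg_fs,
#'   r_peak_times, duration, profile
#' @export
simulate_record <- function(profile, duration, ecg_fs = 130, ppg_fs = 64) {
  ecg <- generate_ecg(profile, duration, ecg_fs)
  ppg <- generate_ppg_from_ecg(ecg$r_peaks, duration, ppg_fs,
                               lag = profile$ppg_lag)
  if (profile$artifact_level > 0) {
    ppg <- add_motion_artifacts(ppg, ppg_fs, profile$artifact_level,
                                seed = profile$seed + 7L)
  }
  structure(list(subject_id = profile$subject_id,
                 ecg = ecg$samples, ecg_fs = ecg_fs,
                 ppg = ppg, ppg_fs = ppg_fs,
                 r_peak_times = ecg$r_peaks,
                 duration = duration, profile = profile),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record %s: %.0f s, ECG %g Hz (%d), PPG %g Hz (%d), %d beats>\n",
              x$subject_id, x$duration, x$ecg_fs, length(x$ecg),
              x$ppg_fs, length(x$ppg), length(x$r_peak_times)))
  invisible(x)
}

#' Write a cohort to a directory tree of delimited text files
#'
#' One directory per subject containing \code{ecg.csv} and \code{ppg.csv}
#' (columns \code{time_s}, \code{value}), \code{r_peaks.csv} (ground truth),
#' and a \code{meta.json} sidecar.
#'
#' @param cohort list of \code{signal_record}
#' @param dir output directory
#' @return invisibly, the vector of subject directories written
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort, function(rec) {
    d <- file.path(dir, rec$subject_id)
    dir.create(d, showWarnings = FALSE)
    te <- (seq_along(rec$ecg) - 1) / rec$ecg_fs
    tp <- (seq_along(rec$ppg) - 1) / rec$ppg_fs
    utils::write.csv(data.frame(time_s = te, value = rec$ecg),
                     file.path(d, "ecg.csv"), row.names = FALSE)
    utils::write.csv(data.frame(time_s = tp, value = rec$ppg),
                     file.path(d, "ppg.csv"), row.names = FALSE)
    utils::write.csv(data.frame(time_s = rec$r_peak_times),
                     file.path(d, "r_peaks.csv"), row.names = FALSE)
    meta <- list(subject_id = rec$subject_id, ecg_fs = rec$ecg_fs,
                 ppg_fs = rec$ppg_fs, duration = rec$duration,
                 profile = unclass(rec$profile))
    jsonlite::write_json(meta, file.path(d, "meta.json"), auto_unbox = TRUE)
    d
  }, character(1))
  invisible(paths)
}

#' Read a cohort previously written by \code{\link{write_cohort}}
#'
#' @param dir cohort directory
#' @return list of \code{signal_record}
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  lapply(subs, function(d) {
    meta <- jsonlite::read_json(file.path(d, "meta.json"), simplifyVector = TRUE)
    ecg <- utils::read.csv(file.path(d, "ecg.csv"))
    ppg <- utils::read.csv(file.path(d, "ppg.csv"))
    rp <- utils::read.csv(file.path(d, "r_peaks.csv"))
    prof <- meta$profile
    profile <- subject_profile(prof$subject_id, prof$mean_hr, prof$hrv_sd,
                               unlist(prof$ecg_amplitudes), prof$ppg_lag,
                               prof$artifact_level, prof$seed)
    structure(list(subject_id = meta$subject_id,
                   ecg = ecg$value, ecg_fs = meta$ecg_fs,
                   ppg = ppg$value, ppg_fs = meta$ppg_fs,
                   r_peak_times = rp$time_s,
                   duration = meta$duration, profile = profile),
              class = "signal_record")
  })
}
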