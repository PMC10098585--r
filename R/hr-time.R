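#' Detect systolic peaks in the normalized pulse signal
#'
#' Local maxima of the normalized signal exceeding `threshold` (0.5 by
#' default; diastolic peaks sit near 0 or below, so the threshold excludes
#' them) separated by at least `min_separation_s`. When two candidates fall
#' closer than the separation, the larger is kept. The peak time is the time
#' of the maximum sample, with no sub-sample interpolation.
#'
#' @param r Normalized sample vector (values roughly in \[-1, 1\]).
#' @param fs Sampling rate, Hz.
#' @param threshold Peak height threshold on the normalized scale.
#' @param min_separation_s Minimum peak separation in seconds (0.25 s = a
#'   240 BPM physiological ceiling).
#' @param t0 Time of the first sample, seconds.
#' @return Vector of peak times in seconds (may be empty, with a warning).
#' @details The moving-max normalization pins the whole systolic ascent at
#'   exactly 1, so maxima are detected plateau-aware: the peak sample of a
#'   run of tied maxima is its last sample, which is where the underlying
#'   pulse signal is largest.
#' @export
detect_systolic_peaks <- function(r, fs, threshold = 0.5,
                                  min_separation_s = 0.25, t0 = 0) {
  r <- as.numeric(r)
  n <- length(r)
  min_dist <- max(1L, round(min_separation_s * fs))
  # Plateau-aware local maxima: r[i] >= left neighbour, r[i] > right
  # neighbour (so a flat top yields its last sample).
  left <- c(-Inf, r[-n])
  right <- c(r[-1], -Inf)
  cand <- which(r >= threshold & r >= left & r > right)
  # A maximum needs real neighbours: a pulse truncated by the record
  # boundary is not a beat.
  cand <- cand[cand > 1L & cand < n]
  if (length(cand) == 0) {
    warn("No systolic peaks found above the threshold.")
    return(numeric(0))
  }
  # Greedy min-separation: accept by descending height, earlier index wins
  # ties; candidates closer than min_dist to an accepted peak are dropped.
  ord <- cand[order(-r[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (!any(abs(accepted - i) < min_dist)) accepted <- c(accepted, i)
  }
  t0 + (sort(accepted) - 1) / fs
}

#' Beat-to-beat periods and instantaneous heart rate
#'
#' Periods are the differences between successive systolic peak times,
#' `T0[k] = peak[k] - peak[k-1]`; instantaneous HR is `60 / T0` in BPM.
#'
#' @param peak_times Systolic peak times in seconds (>= 2).
#' @return A tibble with columns `time_s` (the later peak of each pair),
#'   `period_s`, `inst_hr`.
#' @export
instantaneous_hr <- function(peak_times) {
  if (length(peak_times) < 2) {
    abort_data("Need at least 2 peaks to compute beat periods.")
  }
  periods <- diff(peak_times)
  tibble(time_s = peak_times[-1], period_s = periods, inst_hr = 60 / periods)
}

#' Flag and replace heart-rate outliers
#'
#' A beat is an outlier when its HR deviates from the local median by more
#' than `n_mads` scaled MADs (scale factor 1.4826, the normal-consistency
#' constant), both computed over a centered `window_beats` window that
#' shrinks at the edges. Outliers arise from sharp jolts to the sensor.
#' Flagged values are replaced by the previous beat's cleaned value (the
#' first beat, if flagged, takes its window median); the mask marks replaced
#' beats for exclusion from downstream statistics.
#'
#' When the peak times sit on a coarse sampling grid, beat periods quantize
#' to adjacent sample counts and a window's MAD can collapse to zero even
#' though the spread is pure measurement resolution; supplying `fs` floors
#' the deviation scale at one quantization step of instantaneous HR,
#' `median^2 / (60 * fs)`, so grid jitter is never flagged.
#'
#' @param inst_hr Instantaneous HR vector, BPM.
#' @param window_beats Centered window length in beats (default 40).
#' @param n_mads Outlier threshold in scaled MADs (default 3).
#' @param fs Optional sampling rate (Hz) of the underlying record, enabling
#'   the quantization floor on the deviation scale.
#' @return A list with `hr` (cleaned vector) and `outlier` (logical mask).
#' @export
replace_outliers <- function(inst_hr, window_beats = 40, n_mads = 3,
                             fs = NULL) {
  if (window_beats < 3) abort_config("`window_beats` must be at least 3.")
  n <- length(inst_hr)
  if (n == 0) abort_data("Empty heart-rate sequence.")
  lo_off <- floor((window_beats - 1) / 2)
  hi_off <- window_beats - 1 - lo_off
  med <- numeric(n)
  dev_ok <- logical(n)
  for (k in seq_len(n)) {
    win <- inst_hr[max(1, k - lo_off):min(n, k + hi_off)]
    m <- median(win)
    s <- mad(win, center = m) # 1.4826-scaled by default
    if (!is.null(fs)) s <- max(s, m^2 / (60 * fs))
    med[k] <- m
    dev_ok[k] <- abs(inst_hr[k] - m) <= n_mads * s
  }
  outlier <- !dev_ok
  if (all(outlier)) {
    abort_data("Every beat was flagged as an outlier; signal unusable.")
  }
  hr <- inst_hr
  for (k in which(outlier)) {
    hr[k] <- if (k == 1) med[k] else hr[k - 1]
  }
  list(hr = hr, outlier = outlier)
}

#' Smooth heart rate over a moving beat window
#'
#' Centered moving mean over up to `window_beats` beats (about 30 s at
#' typical rates), emitted at every beat; the window shrinks at the series
#' edges. Beats masked as outliers are excluded from each window's average.
#'
#' @param hr Cleaned instantaneous HR vector, BPM.
#' @param window_beats Window length in beats (default 40).
#' @param mask Logical vector of beats to exclude (outliers).
#' @return Smoothed HR vector, same length.
#' @export
smooth_hr <- function(hr, window_beats = 40, mask = NULL) {
  n <- length(hr)
  if (n == 0) abort_data("Empty heart-rate sequence.")
  mask <- mask %||% rep(FALSE, n)
  lo_off <- floor((window_beats - 1) / 2)
  hi_off <- window_beats - 1 - lo_off
  use <- ifelse(mask, NA_real_, hr)
  cs <- cumsum(c(0, ifelse(is.na(use), 0, use)))
  cnt <- cumsum(c(0, !is.na(use)))
  lo <- pmax(seq_len(n) - lo_off, 1L)
  hi <- pmin(seq_len(n) + hi_off, n)
  tot <- cs[hi + 1] - cs[lo]
  m <- cnt[hi + 1] - cnt[lo]
  out <- ifelse(m > 0, tot / m, NA_real_)
  # Window entirely masked (pathological): fall back to the cleaned values.
  if (anyNA(out)) {
    fallback <- (cumsum(c(0, hr))[hi + 1] - cumsum(c(0, hr))[lo]) / (hi - lo + 1)
    out[is.na(out)] <- fallback[is.na(out)]
  }
  out
}

#' Beat-by-beat heart rate from a preprocessed signal
#'
#' Runs systolic peak detection on the normalized signal, computes beat
#' periods and instantaneous HR, replaces local-MAD outliers, and smooths
#' over a 40-beat window. The first detected peak has no preceding period
#' and carries `NA` for the period-derived columns.
#'
#' @param processed A `ppg_processed` tibble from [ppg_preprocess()].
#' @param config A [roma_config()].
#' @return A tibble of class `beat_train` with columns `beat`, `time_s`,
#'   `period_s`, `inst_hr`, `outlier`, `hr_clean`, `hr_smooth`.
#' @export
hr_time_beats <- function(processed, config = roma_config()) {
  fs <- attr(processed, "fs")
  peaks <- detect_systolic_peaks(processed$normalized, fs,
                                 threshold = config$peak_threshold,
                                 min_separation_s = config$min_separation_s,
                                 t0 = processed$time_s[[1]])
  if (length(peaks) < 2) {
    abort_data("Fewer than 2 systolic peaks detected; cannot form beat periods.")
  }
  ih <- instantaneous_hr(peaks)
  cl <- replace_outliers(ih$inst_hr, config$outlier_window_beats,
                         config$outlier_n_mads, fs = fs)
  sm <- smooth_hr(cl$hr, config$smooth_window_beats, mask = cl$outlier)
  out <- tibble(
    beat = seq_along(peaks),
    time_s = peaks,
    period_s = c(NA_real_, ih$period_s),
    inst_hr = c(NA_real_, ih$inst_hr),
    outlier = c(FALSE, cl$outlier),
    hr_clean = c(NA_real_, cl$hr),
    hr_smooth = c(NA_real_, sm)
  )
  structure(out, class = c("beat_train", class(out)), fs = fs,
            outlier_fraction = mean(cl$outlier))
}
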