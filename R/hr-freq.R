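#' Spectrogram of the pulse signal
#'
#' Magnitude-squared short-time Fourier transform of the high-passed pulse
#' sequence with a Hamming taper, frame length `round(window_s * fs)` and hop
#' `round(hop_s * fs)`. Frames are zero-padded to the next power of two at or
#' above four times the frame length, so peak/width measurements resolve
#' sub-bin variation. Each frame's spectrum is normalized to unit peak so
#' slow amplitude changes over a trial do not distract from the frequency
#' content. Defaults give an HR estimate roughly every 7.27 s from 30 s
#' windows; for 10 s records use `window_s = 2.5`, `hop_s = 0.6`.
#'
#' @param v Sample vector (high-passed pulse signal).
#' @param fs Sampling rate, Hz.
#' @param window_s Frame length in seconds.
#' @param hop_s Hop between frame starts in seconds.
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `spectral_track`: a list with `frames` (tibble
#'   `frame`, `time_s`, `peak_hr`, `line_width`), `power` (frequency x frame
#'   matrix, unit peak per frame), `freq` (Hz), `fs`, `window_s`, `hop_s`.
#' @export
compute_spectrogram <- function(v, fs, window_s = 30, hop_s = 7.27, t0 = 0) {
  L <- round(window_s * fs)
  hop <- max(1L, round(hop_s * fs))
  n <- length(v)
  if (n < L) {
    abort_data(paste0(
      "Record (", round(n / fs, 2), " s) is shorter than one spectrogram ",
      "window (", window_s, " s); use a shorter window, e.g. window_s = 2.5, ",
      "hop_s = 0.6 for 10 s records."
    ))
  }
  starts <- seq(1L, n - L + 1L, by = hop)
  nfft <- 2^ceiling(log2(4 * L))
  nfreq <- nfft %/% 2 + 1L
  taper <- signal::hamming(L)
  power <- matrix(0, nrow = nfreq, ncol = length(starts))
  for (j in seq_along(starts)) {
    frame <- v[starts[j]:(starts[j] + L - 1L)] * taper
    spec <- Mod(fft(c(frame, numeric(nfft - L))))[seq_len(nfreq)]^2
    power[, j] <- spec / max(spec)
  }
  frames <- tibble(
    frame = seq_along(starts),
    time_s = t0 + (starts - 1 + (L - 1) / 2) / fs,
    peak_hr = NA_real_,
    line_width = NA_real_
  )
  structure(
    list(frames = frames, power = power,
         freq = (seq_len(nfreq) - 1) * fs / nfft,
         fs = fs, window_s = window_s, hop_s = hop_s),
    class = "spectral_track"
  )
}

#' @export
print.spectral_track <- function(x, ...) {
  cat(sprintf(
    "<spectral_track>  %d frames (%g s window, %g s hop), %d frequency bins\n",
    nrow(x$frames), x$window_s, x$hop_s, length(x$freq)
  ))
  print(x$frames, ...)
  invisible(x)
}

#' Track the heart-rate spectral line and its width
#'
#' Per frame, the peak HR is 60 times the argmax frequency of the power
#' spectrum within the search band — the peak fundamental, whose power is
#' taken as the frame's unit reference — and the line width is 60 times the
#' frequency extent of the supra-level region: from the lowest to the
#' highest frequency in the band where power reaches `width_level` times
#' the peak power (half maximum by default), with linear interpolation at
#' the two crossings. On a clean record this region is the peak's own main
#' lobe and the width is narrow and stable; impulsive contact-loss
#' artifacts scatter supra-level power across the band and the width jumps
#' to tens of BPM for the affected frames.
#'
#' @param track A `spectral_track` from [compute_spectrogram()].
#' @param band_bpm Search band in BPM, default c(40, 210): the lower bound
#'   excludes respiratory peaks, the upper equals the 3.5 Hz low-pass edge.
#' @param width_level Width measurement level on the unit-normalized linear
#'   power scale.
#' @return The track with `peak_hr` and `line_width` filled in.
#' @export
track_peak_and_width <- function(track, band_bpm = c(40, 210),
                                 width_level = 0.5) {
  stopifnot(inherits(track, "spectral_track"))
  f <- track$freq
  in_band <- f >= band_bpm[[1]] / 60 & f <= band_bpm[[2]] / 60
  if (band_bpm[[2]] / 60 > track$fs / 2) {
    abort_config("Search band exceeds the Nyquist frequency.")
  }
  if (!any(in_band)) abort_config("Empty search band.")
  band_idx <- which(in_band)
  nfr <- ncol(track$power)
  peak_hr <- numeric(nfr)
  width <- numeric(nfr)
  for (j in seq_len(nfr)) {
    p <- track$power[, j]
    ipk <- band_idx[which.max(p[band_idx])]
    peak_hr[j] <- 60 * f[ipk]
    width[j] <- 60 * supralevel_extent(f, p, band_idx, width_level * p[ipk])
  }
  track$frames$peak_hr <- peak_hr
  track$frames$line_width <- width
  track
}

# Frequency extent of the supra-level region within the band: from the
# lowest to the highest bin with power >= level, with linear interpolation
# at the outward crossings (reduces to the peak's FWHM on a clean line).
supralevel_extent <- function(f, p, band_idx, level) {
  above <- band_idx[p[band_idx] >= level]
  i_lo <- min(above)
  i_hi <- max(above)
  lo <- if (i_lo == 1 || p[i_lo - 1] >= level) f[i_lo] else {
    f[i_lo] - (f[i_lo] - f[i_lo - 1]) * (p[i_lo] - level) /
      (p[i_lo] - p[i_lo - 1])
  }
  n <- length(p)
  hi <- if (i_hi == n || p[i_hi + 1] >= level) f[i_hi] else {
    f[i_hi] + (f[i_hi + 1] - f[i_hi]) * (p[i_hi] - level) /
      (p[i_hi] - p[i_hi + 1])
  }
  hi - lo
}

#' Frequency-domain heart rate at beat time stamps
#'
#' Linearly interpolates the per-frame spectral peak HR onto the systolic
#' peak times found in the time domain, for point-by-point comparison of the
#' two domains.
#'
#' @param track A `spectral_track` with `peak_hr` filled in.
#' @param beat_times Target times in seconds.
#' @return A tibble with columns `time_s`, `hr` (frequency-domain source).
#' @export
hr_freq_series <- function(track, beat_times) {
  stopifnot(inherits(track, "spectral_track"))
  if (nrow(track$frames) < 2) {
    abort_data("Need at least 2 spectrogram frames to interpolate.")
  }
  if (anyNA(track$frames$peak_hr)) {
    abort_data("Track has no peak_hr; run track_peak_and_width() first.")
  }
  s <- hr_series(track$frames$time_s, track$frames$peak_hr,
                 source = "frequency_domain")
  align_to_times(s, beat_times)
}
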