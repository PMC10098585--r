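#' Moving-mean baseline (slow drift) estimate
#'
#' Estimates the slow non-periodic baseline (breathing, sweating, adhesive
#' tension) by a centered moving mean over `window_s` seconds, which smooths
#' out the sub-0.3 s systolic/diastolic peaks while following the drift.
#' The window length is `L = round(window_s * fs)` samples (30 at the 46.3 Hz
#' default) and shrinks at the record edges rather than padding. The filter's
#' Dirichlet frequency response has its first null at `fs / L` Hz.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 0.6 s).
#' @return Baseline vector, same length as `x`.
#' @export
moving_mean_baseline <- function(x, fs, window_s = 0.6) {
  if (length(x) == 0) abort_data("Empty input sequence.")
  L <- round(window_s * fs)
  if (L < 1) abort_config("`window_s * fs` must be at least 1 sample.")
  n <- length(x)
  lo_off <- floor((L - 1) / 2)
  hi_off <- L - 1 - lo_off
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - lo_off, 1L)
  hi <- pmin(seq_len(n) + hi_off, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Subtract the baseline drift (time-domain high pass)
#'
#' `v = x - y`: removing the moving-mean baseline is equivalent to filtering
#' with `delta(n) - h`, i.e. a high-pass whose stopband is the mean filter's
#' passband.
#'
#' @param x Raw sample vector.
#' @param baseline Baseline vector from [moving_mean_baseline()].
#' @return High-passed vector `v`, same length.
#' @export
highpass_subtract <- function(x, baseline) {
  if (length(x) != length(baseline)) {
    abort_data("`x` and `baseline` must have the same length.")
  }
  x - baseline
}

# Zero-phase IIR filtering with odd-symmetric edge padding (reduces the
# start/end transients of plain forward-backward filtering).
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) + 9L)
  if (pad < 1L) return(signal::filtfilt(b, a, x))
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(b, a, c(pre, x, post))
  y[(pad + 1):(pad + n)]
}

# Minimum-order elliptic low-pass to the stated pass/stop spec. The design
# targets are halved in dB per pass because the filter is applied
# forward-backward: the zero-phase response then shows <= 0.5 dB passband
# ripple and >= 60 dB stopband attenuation.
design_lowpass <- function(fs, cutoff_hz = 3.5, steepness = 0.8) {
  nyq <- fs / 2
  if (cutoff_hz >= nyq) {
    abort_config("`cutoff_hz` must be below the Nyquist frequency.")
  }
  if (steepness <= 0 || steepness >= 1) {
    abort_config("`steepness` must be in (0, 1).")
  }
  stop_hz <- cutoff_hz + (1 - steepness) * (nyq - cutoff_hz)
  ord <- signal::ellipord(cutoff_hz / nyq, stop_hz / nyq, 0.25, 31)
  signal::ellip(ord)
}

#' Low-pass filter the pulse signal
#'
#' Zero-phase recursive (elliptic) low-pass at `cutoff_hz` (3.5 Hz = 210 BPM
#' by default) to remove high-frequency noise while preserving the heart-rate
#' signal. `steepness` sets the transition width: the stopband edge sits at
#' `cutoff_hz + (1 - steepness) * (fs/2 - cutoff_hz)`. The zero-phase
#' response has passband ripple within 0.5 dB and stopband attenuation of at
#' least 60 dB, and leaves systolic peak timing undistorted.
#'
#' @param v High-passed sample vector.
#' @param fs Sampling rate, Hz.
#' @param cutoff_hz Passband edge in Hz.
#' @param steepness Roll-off fraction in (0, 1); larger = sharper.
#' @return Filtered vector `z`, same length.
#' @export
lowpass_pulse <- function(v, fs, cutoff_hz = 3.5, steepness = 0.8) {
  filt <- design_lowpass(fs, cutoff_hz, steepness)
  zero_phase_filter(filt$b, filt$a, v)
}

# Elliptic band-stop notch. Passband edges sit at center -/+ 0.54 * width so
# that the measured zero-phase -3 dB width equals the requested width; 18 dB
# per-pass stopband gives >= 36 dB rejection at the center after the
# forward-backward application.
design_notch <- function(fs, center_bpm = 100, width_bpm = 50) {
  nyq <- fs / 2
  f_lo <- (center_bpm - 0.54 * width_bpm) / 60
  f_hi <- (center_bpm + 0.54 * width_bpm) / 60
  if ((center_bpm + width_bpm / 2) / 60 >= nyq || f_hi >= nyq) {
    abort_config("Notch band exceeds the Nyquist frequency.")
  }
  if (f_lo <= 0) abort_config("Notch band extends below 0 Hz.")
  signal::ellip(3, 0.25, 18, c(f_lo, f_hi) / nyq, type = "stop")
}

#' Notch out a pedaling-cadence artifact
#'
#' Zero-phase IIR band-stop centered at `center_bpm` (default 100 BPM, twice
#' a 50 RPM pedaling cadence) with a -3 dB width of `width_bpm`. Attenuation
#' at the center exceeds 30 dB while frequencies 30 BPM away from the center
#' pass within 1 dB, so a true heart-rate line at, say, 130 BPM is untouched.
#'
#' @param v Sample vector (typically the high-passed sequence).
#' @param fs Sampling rate, Hz.
#' @param center_bpm Notch center in BPM.
#' @param width_bpm -3 dB width in BPM.
#' @return Filtered vector, same length.
#' @export
notch_cadence <- function(v, fs, center_bpm = 100, width_bpm = 50) {
  filt <- design_notch(fs, center_bpm, width_bpm)
  zero_phase_filter(filt$b, filt$a, v)
}

#' Moving-maximum amplitude tracking and normalization
#'
#' Tracks the systolic peak amplitude with a trailing moving maximum over
#' `window_s` seconds (`w`), then normalizes the pulse signal by it
#' (`r = v / max(w, eps)` with `eps = 1e-6 * max(abs(v))` guarding division),
#' so that systolic peaks all sit at +1 regardless of the slow amplitude
#' changes over a trial.
#'
#' @param v Sample vector (drift-free pulse signal).
#' @param fs Sampling rate, Hz.
#' @param window_s Trailing window in seconds (default 0.5 s).
#' @return A list with `w` (moving max) and `r` (normalized signal).
#' @export
normalize_moving_max <- function(v, fs, window_s = 0.5) {
  L <- max(1L, round(window_s * fs))
  if (all(v == 0)) {
    warn("All-zero input; returning an all-zero normalized signal.")
    return(list(w = v, r = v))
  }
  w <- zoo::rollapplyr(v, width = L, FUN = max, partial = TRUE)
  eps <- 1e-6 * max(abs(v))
  list(w = w, r = v / pmax(w, eps))
}

#' Run the full preprocessing chain
#'
#' Produces the drift-free, band-limited, amplitude-normalized pulse signal
#' from raw samples: moving-mean baseline `y`, high-passed `v = x - y`,
#' optional cadence notch, zero-phase low-passed `z`, trailing moving max
#' `w` and normalized `r = z / w`. The spectrogram consumes `v` (before the
#' low pass); `z` feeds time-domain peak picking.
#'
#' @param record A [ppg_record()] (or data frame with `time_s`, `ppg` plus
#'   an `fs` attribute).
#' @param config A [roma_config()] list of tunables.
#' @return A tibble of class `ppg_processed` with columns `time_s`, `raw`,
#'   `baseline`, `highpassed`, `lowpassed`, `moving_max`, `normalized`,
#'   carrying `fs` as an attribute.
#' @export
ppg_preprocess <- function(record, config = roma_config()) {
  fs <- ppg_fs(record)
  x <- record$ppg
  y <- moving_mean_baseline(x, fs, config$baseline_window_s)
  v <- highpass_subtract(x, y)
  if (isTRUE(config$notch)) {
    v <- notch_cadence(v, fs, config$notch_center_bpm, config$notch_width_bpm)
  }
  z <- lowpass_pulse(v, fs, config$lowpass_hz, config$steepness)
  nm <- normalize_moving_max(z, fs, config$max_window_s)
  out <- tibble(
    time_s = record$time_s,
    raw = x, baseline = y, highpassed = v, lowpassed = z,
    moving_max = nm$w, normalized = nm$r
  )
  structure(out, class = c("ppg_processed", class(out)),
            fs = fs, record_id = record_id(record),
            notch_applied = isTRUE(config$notch))
}
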