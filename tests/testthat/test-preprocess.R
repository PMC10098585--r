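test_that("moving-mean baseline is exact on constants, impulses and is linear", {
  fs <- 46.3
  expect_equal(moving_mean_baseline(rep(3.7, 200), fs), rep(3.7, 200))

  # unit impulse with an L = 30 window -> rectangle of height 1/30
  x <- numeric(200); x[100] <- 1
  y <- moving_mean_baseline(x, fs, window_s = 30 / fs)
  expect_equal(max(y), 1 / 30)
  expect_equal(sum(y > 0), 30)

  set.seed(11)
  a <- rnorm(300); b <- rnorm(300)
  expect_equal(moving_mean_baseline(2 * a - 3 * b, fs),
               2 * moving_mean_baseline(a, fs) - 3 * moving_mean_baseline(b, fs))

  expect_error(moving_mean_baseline(numeric(0), fs), class = "romahr_data_error")
})

test_that("moving mean nulls a sinusoid at fs/L (first Dirichlet null)", {
  fs <- 46.3; L <- 30
  t <- (0:9999) / fs
  x <- sin(2 * pi * (fs / L) * t)
  y <- moving_mean_baseline(x, fs, window_s = L / fs)
  interior <- 100:9900
  expect_lt(sqrt(mean(y[interior]^2)) / sqrt(mean(x^2)), 1e-6)
})

test_that("measured first-null frequency of the L=30 filter equals fs/30", {
  fs <- 46.3
  h <- rep(1 / 30, 30)
  nfft <- 2^16
  H <- Mod(fft(c(h, numeric(nfft - 30))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  null_idx <- which(diff(sign(diff(H))) > 0)[1] + 1 # first local minimum
  expect_equal(f[null_idx], fs / 30, tolerance = fs / nfft / (fs / 30))
  expect_lt(H[null_idx], 1e-3)
})

test_that("baseline subtraction removes drift and keeps the pulse band", {
  fs <- 46.3
  t <- (0:(60 * fs)) / fs
  x <- rep(5, length(t))
  v <- highpass_subtract(x, moving_mean_baseline(x, fs))
  expect_equal(v, numeric(length(t)))

  # band-limited drift below fs/(2L) is removed; a 1.5 Hz pulse train survives
  s <- pulse_waveform(1.5 * t)
  drift <- 0.5 * sin(2 * pi * 0.2 * t)
  v2 <- highpass_subtract(s + drift, moving_mean_baseline(s + drift, fs))
  interior <- 200:(length(t) - 200)
  resid <- v2[interior] - highpass_subtract(s, moving_mean_baseline(s, fs))[interior]
  expect_lt(sqrt(mean(resid^2)) / sqrt(mean(s[interior]^2)), 0.05)

  expect_error(highpass_subtract(1:3, 1:4), class = "romahr_data_error")
})

test_that("zero-phase low-pass meets its passband and stopband contract", {
  fs <- 46.3
  filt <- romahr:::design_lowpass(fs)
  H <- signal::freqz(filt$b, filt$a, n = 4096, Fs = fs)
  g_db <- 2 * 20 * log10(Mod(H$h)) # zero-phase application squares |H|
  f <- H$f
  stop_edge <- 3.5 + 0.2 * (fs / 2 - 3.5)
  expect_lt(abs(g_db[1]), 0.5)                        # DC
  expect_lt(abs(g_db[which.min(abs(f - 1))]), 0.5)    # 60 BPM tone
  expect_true(all(abs(g_db[f <= 3.5]) <= 0.5 + 1e-6)) # passband ripple
  expect_true(all(g_db[f >= stop_edge] <= -60))       # stopband

  # time domain: a stopband tone is crushed, a 1 Hz tone passes
  t <- (0:(40 * fs)) / fs
  interior <- 300:(length(t) - 300)
  hi <- sin(2 * pi * stop_edge * t)
  z <- lowpass_pulse(hi, fs)
  expect_lt(sqrt(mean(z[interior]^2)) / sqrt(mean(hi^2)), 1e-3)
  lo <- sin(2 * pi * 1 * t)
  z2 <- lowpass_pulse(lo, fs)
  expect_equal(sqrt(mean(z2[interior]^2)) / sqrt(mean(lo[interior]^2)), 1,
               tolerance = 0.06)

  expect_error(lowpass_pulse(1:10, fs = 6, cutoff_hz = 3.5),
               class = "romahr_config_error")
})

test_that("cadence notch rejects 100 BPM and passes neighbours", {
  fs <- 46.3
  t <- (0:(60 * fs)) / fs
  interior <- 300:(length(t) - 300)
  rms <- function(x) sqrt(mean(x[interior]^2))

  tone100 <- sin(2 * pi * (100 / 60) * t)
  expect_lt(rms(notch_cadence(tone100, fs)) / rms(tone100), 0.03)

  tone70 <- sin(2 * pi * (70 / 60) * t)
  ratio <- rms(notch_cadence(tone70, fs)) / rms(tone70)
  expect_gt(20 * log10(ratio), -1) # within 1 dB

  expect_equal(notch_cadence(numeric(500), fs), numeric(500))
  expect_error(notch_cadence(1:10, fs = 4, center_bpm = 100, width_bpm = 50),
               class = "romahr_config_error")
})

test_that("moving-max normalization is scale invariant and pins peaks at 1", {
  fs <- 46.3
  t <- (0:(10 * fs)) / fs
  v <- pulse_waveform(1.2 * t)
  r1 <- normalize_moving_max(v, fs)$r
  r2 <- normalize_moving_max(7.3 * v, fs)$r
  expect_equal(r1, r2)

  # adjacent pulses of different amplitude both normalize to 1
  v2 <- numeric(100)
  v2[20] <- 2; v2[60] <- 4
  r <- normalize_moving_max(v2, fs = 46.3, window_s = 0.5)$r
  expect_equal(r[20], 1)
  expect_equal(r[60], 1)

  # idempotence: normalizing an already-normalized train keeps peaks at 1
  rr <- normalize_moving_max(r, fs = 46.3, window_s = 0.5)$r
  expect_equal(max(rr[15:25]), 1)
  expect_equal(max(rr[55:65]), 1)

  expect_warning(out <- normalize_moving_max(numeric(50), fs), "zero")
  expect_equal(out$r, numeric(50))
})

test_that("preprocessing preserves systolic peak timing to within a sample", {
  fs <- 46.3
  syn <- quick_synth(hr = 70, duration_s = 120, seed = 21,
                     drift_amp = 0, noise_sd = 0)
  proc <- ppg_preprocess(syn$record)
  got <- detect_systolic_peaks(proc$normalized, fs)
  # reference: peaks of the raw clean pulse signal itself
  raw <- syn$record$ppg
  nm <- normalize_moving_max(raw, fs)
  want <- detect_systolic_peaks(nm$r, fs)
  n <- min(length(got), length(want))
  expect_gt(n, 100)
  expect_lt(max(abs(got[1:n] - want[1:n])), 1 / fs + 1e-9)
})
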