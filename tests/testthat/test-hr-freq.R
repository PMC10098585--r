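test_that("spectrogram frames localize a pure tone and count correctly", {
  fs <- 46.3
  rec <- tone_record(1.2, fs = fs, duration_s = 120)
  tr <- compute_spectrogram(rec$ppg, fs)
  arg <- apply(tr$power, 2, which.max)
  expect_true(all(abs(tr$freq[arg] - 1.2) <= 1 / 30))
  expect_equal(apply(tr$power, 2, max), rep(1, ncol(tr$power)))

  # hop = window on a 60 s record: exactly 2 frames
  tr2 <- compute_spectrogram(rec$ppg[1:round(60 * fs)], fs,
                             window_s = 30, hop_s = 30)
  expect_equal(nrow(tr2$frames), 2)

  err <- tryCatch(compute_spectrogram(rnorm(100), fs),
                  error = function(e) conditionMessage(e))
  expect_match(err, "shorter window")
})

test_that("white-noise frames have an unstable argmax", {
  set.seed(14)
  fs <- 46.3
  x <- rnorm(round(120 * fs))
  tr <- track_peak_and_width(compute_spectrogram(x, fs))
  expect_gt(length(unique(round(tr$frames$peak_hr))), 3)
})

test_that("peak tracking reads tones, prefers the larger peak, widens on noise", {
  fs <- 46.3
  tr <- track_peak_and_width(compute_spectrogram(tone_record(1)$ppg, fs))
  expect_equal(tr$frames$peak_hr, rep(60, nrow(tr$frames)), tolerance = 0.005)
  expect_lt(sd(tr$frames$line_width), 0.1)
  expect_gt(min(tr$frames$line_width), 2) # at least the 60/window_s resolution

  two <- tone_record(1)$ppg + 0.4 * tone_record(1.67)$ppg
  tr2 <- track_peak_and_width(compute_spectrogram(two, fs))
  expect_equal(tr2$frames$peak_hr, rep(60, nrow(tr2$frames)), tolerance = 0.005)

  set.seed(15)
  trn <- track_peak_and_width(compute_spectrogram(rnorm(round(120 * fs)), fs))
  expect_gt(median(trn$frames$line_width), 3 * median(tr$frames$line_width))

  expect_error(track_peak_and_width(tr, band_bpm = c(100, 90)),
               class = "romahr_config_error")
})

test_that("constant tones anywhere in 45-200 BPM are recovered within one bin", {
  fs <- 46.3
  for (h in c(45, 72, 133, 200)) {
    tr <- track_peak_and_width(compute_spectrogram(tone_record(h / 60)$ppg, fs))
    expect_true(all(abs(tr$frames$peak_hr - h) <= 2))
  }
})

test_that("the asymmetric pulse's fundamental beats its second harmonic", {
  fs <- 46.3
  t <- (0:(120 * fs)) / fs
  v <- pulse_waveform(1.1 * t)
  v <- highpass_subtract(v, moving_mean_baseline(v, fs))
  tr <- track_peak_and_width(compute_spectrogram(v, fs))
  expect_equal(tr$frames$peak_hr, rep(66, nrow(tr$frames)), tolerance = 0.02)
})

test_that("contact-loss impulses broaden the line width at least threefold", {
  clean <- quick_synth(hr = 80, duration_s = 240, seed = 61)
  dirty <- quick_synth(hr = 80, duration_s = 240, seed = 61,
                       contact_loss_rate = 0.05)
  width_of <- function(syn) {
    fs <- ppg_fs(syn$record)
    v <- highpass_subtract(syn$record$ppg,
                           moving_mean_baseline(syn$record$ppg, fs))
    track_peak_and_width(compute_spectrogram(v, fs))$frames$line_width
  }
  w_clean <- width_of(clean)
  w_dirty <- width_of(dirty)
  expect_gt(max(w_dirty), 3 * median(w_clean))
})

test_that("the short-record mode yields an HR value every 0.6 s", {
  syn <- synth_ppg(synth_config(fs = 30, duration_s = 10,
                                hr_trajectory = hr_constant(72), seed = 5))
  tr <- compute_spectrogram(syn$record$ppg, 30, window_s = 2.5, hop_s = 0.6)
  expect_gte(nrow(tr$frames), 12)
})

test_that("frequency-domain HR interpolates onto beat times", {
  fs <- 46.3
  tr <- track_peak_and_width(compute_spectrogram(tone_record(1.2)$ppg, fs))
  out <- hr_freq_series(tr, c(20, 40, 60))
  expect_equal(out$hr, rep(72, 3), tolerance = 0.005)

  # synthetic linear frames: midpoint value, ends held
  fake <- tr
  fake$frames <- tibble::tibble(frame = 1:2, time_s = c(0, 100),
                                peak_hr = c(60, 80), line_width = 3)
  expect_equal(hr_freq_series(fake, 50)$hr, 70)
  expect_equal(hr_freq_series(fake, -10)$hr, 60)

  one <- tr; one$frames <- one$frames[1, ]
  expect_error(hr_freq_series(one, 10), class = "romahr_data_error")
})
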