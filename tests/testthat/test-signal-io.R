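test_that("read_ppg_csv builds records from value-only and timed CSVs", {
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "vals.csv")
  readr::write_csv(tibble::tibble(ppg = c(1, 2, 3)), p1)
  rec <- read_ppg_csv(p1, fs_override = 30)
  expect_s3_class(rec, "ppg_record")
  expect_equal(ppg_fs(rec), 30)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$ppg, c(1, 2, 3))

  p2 <- file.path(tmp, "timed.csv")
  readr::write_csv(tibble::tibble(time_s = (0:99) / 46.3, ppg = rnorm(100)), p2)
  rec2 <- read_ppg_csv(p2)
  expect_equal(ppg_fs(rec2), 46.3, tolerance = 1e-9)

  # fs_override wins over the time column, with a warning
  expect_warning(rec3 <- read_ppg_csv(p2, fs_override = 50), "wins")
  expect_equal(ppg_fs(rec3), 50)
})

test_that("read_ppg_csv rejects malformed inputs", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "shuffled.csv")
  readr::write_csv(tibble::tibble(time_s = c(0, 2, 1), ppg = c(1, 2, 3)), p)
  expect_error(read_ppg_csv(p), class = "romahr_data_error")

  p2 <- file.path(tmp, "nocol.csv")
  readr::write_csv(tibble::tibble(x = 1:3), p2)
  expect_error(read_ppg_csv(p2, fs_override = 30),
               class = "romahr_format_error")

  p3 <- file.path(tmp, "nots.csv")
  readr::write_csv(tibble::tibble(ppg = 1:3), p3)
  expect_error(read_ppg_csv(p3), class = "romahr_config_error")
})

test_that("CSV round trip reproduces samples bit-exactly and fs to 1e-9", {
  tmp <- withr::local_tempdir()
  set.seed(4)
  rec <- ppg_record(rnorm(500), fs = 46.3, record_id = "rt")
  p <- file.path(tmp, "rt.csv")
  write_ppg_csv(rec, p)
  back <- read_ppg_csv(p)
  expect_identical(back$ppg, rec$ppg)
  expect_equal(ppg_fs(back), 46.3, tolerance = 1e-9)
})

test_that("PhysioNet-style records are read with channel selection and scaling", {
  tmp <- withr::local_tempdir()
  digital <- list(ECG = as.integer(round(100 * sin(1:300 / 10))),
                  PPG = as.integer(round(200 * cos(1:300 / 15))))
  base <- write_wfdb_fixture(tmp, "rec30", digital, fs = 30,
                             gain = 100, baseline = 10)
  rec <- read_physionet_record(base)
  expect_equal(ppg_fs(rec), 30)
  expect_equal(nrow(rec), 300)
  expect_equal(rec$ppg, (digital$PPG - 10) / 100)

  # explicit channel selection by index and by name
  ecg <- read_physionet_record(base, channel = 1)
  expect_equal(ecg$ppg, (digital$ECG - 10) / 100)
  expect_equal(read_physionet_record(base, channel = "ECG")$ppg, ecg$ppg)

  # a record with only ECG channels is a data error
  base2 <- write_wfdb_fixture(tmp, "ecgonly", digital["ECG"], fs = 125)
  expect_error(read_physionet_record(base2), class = "romahr_data_error")
  expect_equal(ppg_fs(read_physionet_record(base2, channel = 1)), 125)
})

test_that("format 80 and packed format 212 decode to the same digital values", {
  tmp <- withr::local_tempdir()
  vals <- list(PPG = as.integer(c(0, 1, -1, 100, -100, 127, -128, 5)))
  b80 <- write_wfdb_fixture(tmp, "f80", vals, fmt = 80, gain = 1, baseline = 0)
  expect_equal(read_physionet_record(b80)$ppg, as.numeric(vals$PPG))

  vals212 <- list(PPG = as.integer(c(0, 1, -1, 2047, -2048, 513, -514, 9)))
  b212 <- write_wfdb_fixture(tmp, "f212", vals212, fmt = 212,
                             gain = 1, baseline = 0)
  expect_equal(read_physionet_record(b212)$ppg, as.numeric(vals212$PPG))
})

test_that("align_to_times interpolates linearly and holds endpoints", {
  s <- hr_series(c(0, 10), c(60, 80))
  expect_equal(align_to_times(s, 5)$hr, 70)
  expect_equal(align_to_times(s, 15)$hr, 80)   # held beyond the last point
  expect_equal(align_to_times(s, -5)$hr, 60)   # held before the first point

  s2 <- hr_series(c(0, 2, 4), c(60, 60, 90))
  expect_equal(align_to_times(s2, 3)$hr, 75)

  # identity when target times equal the series times
  expect_equal(align_to_times(s2, s2$time_s)$hr, s2$hr)

  expect_error(align_to_times(hr_series(1, 60), 2), class = "romahr_data_error")
})

test_that("hr_series validates its invariants", {
  expect_error(hr_series(c(0, 0), c(60, 70)), class = "romahr_data_error")
  expect_error(hr_series(c(0, 1), c(60, -5)), class = "romahr_data_error")
  expect_error(hr_series(0:2, c(60, 70)), class = "romahr_data_error")
})
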