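#' Construct a PPG record
#'
#' A PPG record is a tibble with columns `time_s` and `ppg`, carrying the
#' sampling rate and record metadata as attributes. Sample timestamps are
#' 0-based: `time_s = t0 + (n - 1) / fs` for the n-th sample.
#'
#' @param ppg Numeric vector of raw PPG samples (arbitrary sensor units).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time offset in seconds.
#' @param record_id Opaque record identifier.
#' @param quality_label Optional visual-inspection label, `"good"` or
#'   `"poor"`.
#' @return A tibble of class `ppg_record` with columns `time_s`, `ppg`.
#' @examples
#' rec <- ppg_record(sin(2 * pi * seq(0, 10, by = 1 / 30)), fs = 30)
#' rec
#' @export
ppg_record <- function(ppg, fs, t0 = 0, record_id = "record",
                       quality_label = NULL) {
  if (!is.numeric(ppg) || length(ppg) < 1L) {
    abort_data("`ppg` must be a numeric vector with at least one sample.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort_config("`fs` must be a single positive number (Hz).")
  }
  if (!is.null(quality_label)) {
    quality_label <- match.arg(quality_label, c("good", "poor"))
  }
  out <- tibble(
    time_s = t0 + (seq_along(ppg) - 1) / fs,
    ppg = as.numeric(ppg)
  )
  structure(
    out,
    class = c("ppg_record", class(out)),
    fs = fs,
    record_id = as.character(record_id),
    quality_label = quality_label
  )
}

#' Sampling rate and metadata accessors for PPG records
#'
#' @param x A `ppg_record`.
#' @return `ppg_fs()` the sampling rate in Hz; `record_id()` the identifier;
#'   `quality_label()` the annotation (`NA` when absent).
#' @export
ppg_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort_data("Object carries no sampling rate attribute.")
  fs
}

#' @rdname ppg_fs
#' @export
record_id <- function(x) attr(x, "record_id") %||% NA_character_

#' @rdname ppg_fs
#' @export
quality_label <- function(x) attr(x, "quality_label") %||% NA_character_

#' @export
print.ppg_record <- function(x, ...) {
  fs <- attr(x, "fs")
  cat(sprintf(
    "<ppg_record '%s'>  %d samples @ %.4g Hz (%.1f s)%s\n",
    record_id(x), nrow(x), fs, nrow(x) / fs,
    if (!is.na(quality_label(x))) paste0("  [", quality_label(x), "]") else ""
  ))
  NextMethod()
}

#' Read a PPG record from CSV
#'
#' Expects a comma-separated file with a header row and either columns
#' `time_s` and `ppg` (case-insensitive), or a `ppg` column alone together
#' with `fs_override`. When a time column is present the sampling rate is
#' estimated as `1 / median(diff(time_s))` and timestamps are checked for
#' uniformity within 1%. When both a time column and `fs_override` are
#' given, `fs_override` wins and a warning is issued.
#'
#' @param path Path to the CSV file.
#' @param fs_override Optional sampling rate in Hz, required when the file
#'   has no time column.
#' @param record_id Identifier; defaults to the file name.
#' @param quality_label Optional `"good"`/`"poor"` annotation.
#' @return A [ppg_record()].
#' @export
read_ppg_csv <- function(path, fs_override = NULL, record_id = NULL,
                         quality_label = NULL) {
  if (!file.exists(path)) abort_io(paste0("File not found: ", path))
  # Read numerics as text and convert with strtod (correctly rounded), so a
  # write/read cycle reproduces samples bit-exactly.
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  names(df) <- tolower(names(df))
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.numeric))
  if (!"ppg" %in% names(df)) {
    abort_format("CSV must contain a `ppg` column (case-insensitive).")
  }
  has_time <- "time_s" %in% names(df)
  if (!has_time && is.null(fs_override)) {
    abort_config(
      "CSV has no `time_s` column; supply `fs_override` to set the sampling rate."
    )
  }
  t0 <- 0
  if (has_time) {
    tt <- df$time_s
    dt <- diff(tt)
    if (length(dt) >= 1 && any(dt <= 0)) {
      abort_data("`time_s` column must be strictly increasing.")
    }
    t0 <- tt[[1]]
    fs_est <- if (length(dt) >= 1) 1 / median(dt) else NA_real_
    if (length(dt) >= 1 && any(abs(dt - median(dt)) > 0.01 * median(dt))) {
      warn("Timestamps deviate from uniform spacing by more than 1%.")
    }
    if (!is.null(fs_override)) {
      warn("Both a time column and `fs_override` given; `fs_override` wins.")
      fs <- fs_override
    } else {
      if (!is.finite(fs_est)) {
        abort_config("Sampling rate could not be resolved from the time column.")
      }
      fs <- fs_est
    }
  } else {
    fs <- fs_override
  }
  ppg_record(df$ppg, fs = fs, t0 = t0,
             record_id = record_id %||% sub("\\.csv$", "", basename(path)),
             quality_label = quality_label)
}

#' Write a PPG record to CSV
#'
#' Writes the `time_s`/`ppg` dialect read by [read_ppg_csv()]. Full double
#' precision is retained so a round trip reproduces the samples exactly.
#'
#' @param record A [ppg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(record, path) {
  # %.17g guarantees binary64 round-tripping of every sample
  df <- tibble(time_s = sprintf("%.17g", record$time_s),
               ppg = sprintf("%.17g", record$ppg))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Construct a heart-rate series
#'
#' @param times Times in seconds, strictly increasing.
#' @param hr Heart rate in BPM, finite and positive, same length as `times`.
#' @param source One of `"time_domain"`, `"frequency_domain"`, `"reference"`.
#' @return A tibble with columns `time_s`, `hr` and a `source` attribute.
#' @export
hr_series <- function(times, hr, source = c("reference", "time_domain",
                                            "frequency_domain")) {
  source <- match.arg(source)
  if (length(times) != length(hr)) {
    abort_data("`times` and `hr` must have the same length.")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort_data("`times` must be strictly increasing.")
  }
  ok <- is.finite(hr)
  if (any(hr[ok] <= 0)) abort_data("`hr` values must be positive.")
  structure(tibble(time_s = as.numeric(times), hr = as.numeric(hr)),
            source = source)
}

#' Interpolate a heart-rate series onto target times
#'
#' Linear interpolation inside the series' time span; outside the span the
#' endpoint values are held constant. Used to carry the frequency-domain HR
#' back to the systolic time stamps found in the time domain.
#'
#' @param series A data frame with columns `time_s` and `hr` (>= 2 rows).
#' @param target_times Non-empty increasing vector of times in seconds.
#' @return A tibble with columns `time_s` (= `target_times`) and `hr`.
#' @examples
#' s <- hr_series(c(0, 10), c(60, 80))
#' align_to_times(s, 5)  # 70 BPM
#' @export
align_to_times <- function(series, target_times) {
  stopifnot(is.data.frame(series))
  keep <- is.finite(series$hr)
  series <- series[keep, , drop = FALSE]
  if (nrow(series) < 2) {
    abort_data("Need at least 2 finite points to interpolate a heart-rate series.")
  }
  if (length(target_times) < 1) abort_data("`target_times` must be non-empty.")
  fit <- approx(series$time_s, series$hr, xout = target_times, rule = 2,
                ties = "ordered")
  out <- tibble(time_s = as.numeric(target_times), hr = fit$y)
  attr(out, "source") <- attr(series, "source")
  out
}
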