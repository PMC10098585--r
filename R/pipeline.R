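#' Pipeline configuration
#'
#' Collects every tunable of the processing chain with the published
#' defaults: 0.6 s baseline mean, 3.5 Hz low pass with 0.8 steepness, 0.5 s
#' moving max, 0.5 peak threshold, 40-beat / 3-scaled-MAD outlier rule,
#' 40-beat smoothing, 30 s spectrogram window with ~7.27 s hop, a
#' \[40, 210\] BPM search band with half-maximum line widths, 10 BPM
#' self-consistency tolerance, 5 BPM accuracy tolerance, quality cut points
#' of 30 (self-consistency) and 10 BPM (STD-width), and an optional
#' 100/50 BPM cadence notch (off by default). For 10 s records use
#' `roma_config(window_s = 2.5, hop_s = 0.6)`.
#'
#' @param baseline_window_s Moving-mean baseline window, seconds.
#' @param lowpass_hz Low-pass passband edge, Hz.
#' @param steepness Low-pass roll-off fraction in (0, 1).
#' @param notch Apply the cadence notch filter?
#' @param notch_center_bpm,notch_width_bpm Notch center and -3 dB width, BPM.
#' @param max_window_s Trailing moving-max window, seconds.
#' @param peak_threshold Systolic peak height threshold (normalized units).
#' @param min_separation_s Minimum peak separation, seconds.
#' @param outlier_window_beats,outlier_n_mads Outlier rule parameters.
#' @param smooth_window_beats Smoothing window, beats.
#' @param window_s,hop_s Spectrogram frame length and hop, seconds.
#' @param band_bpm HR search band, BPM.
#' @param width_level Line-width measurement level (fraction of unit peak).
#' @param sc_tol_bpm Self-consistency agreement tolerance, BPM.
#' @param accuracy_tol_bpm Accuracy tolerance against the reference, BPM.
#' @param sc_cut,width_cut Quality cut points (percent; BPM).
#' @param rmse_denom RMSE denominator convention, `"paper"` or `"standard"`.
#' @return A list of class `roma_config`.
#' @export
roma_config <- function(baseline_window_s = 0.6,
                        lowpass_hz = 3.5, steepness = 0.8,
                        notch = FALSE,
                        notch_center_bpm = 100, notch_width_bpm = 50,
                        max_window_s = 0.5,
                        peak_threshold = 0.5, min_separation_s = 0.25,
                        outlier_window_beats = 40, outlier_n_mads = 3,
                        smooth_window_beats = 40,
                        window_s = 30, hop_s = 7.27,
                        band_bpm = c(40, 210), width_level = 0.5,
                        sc_tol_bpm = 10, accuracy_tol_bpm = 5,
                        sc_cut = 30, width_cut = 10,
                        rmse_denom = "paper") {
  structure(as.list(environment()), class = "roma_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of `roma_config()` fields; unknown keys are rejected,
#' missing keys take their defaults.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file values.
#' @return A [roma_config()].
#' @export
read_roma_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals <- modifyList(vals, overrides)
  known <- names(formals(roma_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort_config(paste0("Unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(roma_config, vals)
}

#' Process one PPG record end to end
#'
#' Runs the full chain: preprocessing (baseline removal, optional cadence
#' notch, low pass, moving-max normalization), time-domain beat extraction,
#' the spectrogram with peak/width tracking (computed on the pre-lowpass
#' high-passed signal), the two quality indices with the binary label, and
#' — when a reference HR series is supplied — agreement statistics at the
#' beat time stamps (outlier-masked beats excluded).
#'
#' @param record A [ppg_record()].
#' @param config A [roma_config()].
#' @param reference Optional reference HR data frame (`time_s`, `hr`).
#' @return A list of class `roma_result`: `record_id`, `beats` (beat table),
#'   `track` (spectral track), `hr` (beat-aligned tibble with `hr_time`,
#'   `hr_freq`), `quality` (one-row tibble), `agreement` (one-row tibble or
#'   `NULL`), `config`.
#' @export
roma_process <- function(record, config = roma_config(), reference = NULL) {
  fs <- ppg_fs(record)
  proc <- ppg_preprocess(record, config)
  beats <- hr_time_beats(proc, config)

  # Spectrogram consumes the high-passed sequence before the low pass.
  x <- record$ppg
  v <- highpass_subtract(x, moving_mean_baseline(x, fs, config$baseline_window_s))
  if (isTRUE(config$notch)) {
    v <- notch_cadence(v, fs, config$notch_center_bpm, config$notch_width_bpm)
  }
  track <- compute_spectrogram(v, fs, config$window_s, config$hop_s,
                               t0 = record$time_s[[1]])
  track <- track_peak_and_width(track, config$band_bpm, config$width_level)

  cmp <- beats[!is.na(beats$inst_hr), ]
  ht <- tibble(time_s = cmp$time_s, hr = cmp$hr_smooth)
  hf <- hr_freq_series(track, cmp$time_s)
  qual <- quality_metrics(ht, hf, track, config, exclude = cmp$outlier,
                          record_id = record_id(record))
  hr_tbl <- tibble(time_s = cmp$time_s, hr_time = ht$hr, hr_freq = hf$hr,
                   outlier = cmp$outlier)
  agreement <- NULL
  if (!is.null(reference)) {
    ref <- align_to_times(reference, cmp$time_s)
    agreement <- error_metrics(ref, ht, tol_bpm = config$accuracy_tol_bpm,
                               exclude = cmp$outlier,
                               rmse_denom = config$rmse_denom)
    hr_tbl$hr_ref <- ref$hr
  }
  structure(
    list(record_id = record_id(record), beats = beats, track = track,
         hr = hr_tbl, quality = qual, agreement = agreement, config = config),
    class = "roma_result"
  )
}

#' @export
print.roma_result <- function(x, ...) {
  q <- x$quality
  cat(sprintf(
    "<roma_result '%s'>  %d beats, %d frames\n  self-consistency %.2f%%, STD-width %.2f BPM -> %s\n",
    x$record_id, nrow(x$beats), nrow(x$track$frames),
    q$self_consistency, q$std_width, q$label
  ))
  if (!is.null(x$agreement)) {
    a <- x$agreement
    cat(sprintf(
      "  vs reference: RMSE %.2f, MAE %.2f BPM, MAE%% %.2f, accuracy(5 BPM) %.1f%%\n",
      a$rmse, a$mae, a$mae_pct, a$accuracy5
    ))
  }
  invisible(x)
}

#' @export
tidy.roma_result <- function(x, ...) x$hr

#' @export
glance.roma_result <- function(x, ...) {
  out <- x$quality
  out$outlier_fraction <- attr(x$beats, "outlier_fraction")
  if (!is.null(x$agreement)) out <- dplyr::bind_cols(out, x$agreement)
  out
}

#' Evaluate a set of records
#'
#' Dataset-level workflow: processes every record in a manifest, assembles a
#' per-record table of quality indices and (where references exist) error
#' metrics, and computes the two analysis blocks — signal-quality agreement
#' (poor counts under each index, Cohen's kappa against designed/visual
#' labels, point-biserial correlations, ROC cut points) and quality-accuracy
#' association (Pearson correlations of each index with RMSE and MAE).
#'
#' @param manifest Either a manifest YAML path written by
#'   [make_fixture_suite()] or a data frame with columns `record_id`,
#'   `path`, and optionally `truth_path`, `label`, `fs`.
#' @param config A [roma_config()].
#' @param base_dir Directory for relative paths (defaults to the manifest's).
#' @return A list of class `roma_evaluation`: `records` (per-record tibble),
#'   `agreement_part` (counts, kappa, point-biserial, ROC), and
#'   `accuracy_part` (index-error correlations with Fisher-z confidence
#'   intervals).
#' @export
roma_evaluate <- function(manifest, config = roma_config(), base_dir = NULL) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    mf <- yaml::read_yaml(manifest)
    manifest <- dplyr::bind_rows(lapply(mf$records, function(r) {
      as_tibble(r[!vapply(r, is.null, logical(1))])
    }))
  }
  stopifnot(is.data.frame(manifest))
  base_dir <- base_dir %||% "."
  paths <- file.path(base_dir, manifest$path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort_io(paste0("Manifest refers to missing files: ",
                    paste(missing, collapse = ", ")))
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- read_ppg_csv(paths[[i]], record_id = manifest$record_id[[i]])
    ref <- NULL
    if ("truth_path" %in% names(manifest) && !is.na(manifest$truth_path[[i]])) {
      tr <- readr::read_csv(file.path(base_dir, manifest$truth_path[[i]]),
                            show_col_types = FALSE, progress = FALSE)
      ref <- hr_series(tr$time_s, tr$hr, source = "reference")
    }
    res <- roma_process(rec, config, reference = ref)
    row <- glance(res)
    row$label_design <- if ("label" %in% names(manifest)) {
      manifest$label[[i]]
    } else {
      NA_character_
    }
    rows[[i]] <- row
  }
  records <- dplyr::bind_rows(rows)

  has_labels <- "label_design" %in% names(records) &&
    !all(is.na(records$label_design))
  agreement_part <- NULL
  if (has_labels) {
    good <- records$label_design %in% c("good", "adequate")
    agreement_part <- list(
      n_poor_by_self_consistency =
        sum(records$self_consistency <= config$sc_cut),
      n_poor_by_std_width = sum(records$std_width >= config$width_cut),
      n_poor_combined = sum(records$label == "poor")
    )
    if (length(unique(good)) == 2) {
      agreement_part$kappa <- cohens_kappa(
        records$label == "adequate", good
      )
      agreement_part$pb_self_consistency <-
        point_biserial(good, records$self_consistency)
      agreement_part$pb_std_width <- point_biserial(good, records$std_width)
      agreement_part$roc_self_consistency <- roc_cutpoint(
        records$self_consistency, good, "higher_is_good", "self_consistency"
      )
      agreement_part$roc_std_width <- roc_cutpoint(
        records$std_width, good, "higher_is_poor", "std_width"
      )
    } else {
      warn("Only one designed quality class present; kappa/ROC omitted.")
    }
  } else {
    warn("Manifest has no labels; agreement analyses omitted.")
  }

  accuracy_part <- NULL
  if ("rmse" %in% names(records) && sum(is.finite(records$rmse)) >= 3) {
    n <- sum(is.finite(records$rmse))
    cors <- function(metric, err) {
      r <- cor(records[[metric]], records[[err]],
               use = "complete.obs")
      ci <- cor_fisher_ci(r, n)
      tibble(index = metric, error = err, r = r,
             ci_low = ci[[1]], ci_high = ci[[2]])
    }
    accuracy_part <- dplyr::bind_rows(
      cors("self_consistency", "rmse"), cors("self_consistency", "mae"),
      cors("std_width", "rmse"), cors("std_width", "mae")
    )
  }
  structure(list(records = records, agreement_part = agreement_part,
                 accuracy_part = accuracy_part, config = config),
            class = "roma_evaluation")
}

#' @export
print.roma_evaluation <- function(x, ...) {
  cat(sprintf("<roma_evaluation>  %d records\n", nrow(x$records)))
  print(x$records, ...)
  if (!is.null(x$agreement_part)) {
    ap <- x$agreement_part
    cat(sprintf(
      "poor by self-consistency: %d; by STD-width: %d; combined: %d\n",
      ap$n_poor_by_self_consistency, ap$n_poor_by_std_width, ap$n_poor_combined
    ))
    if (!is.null(ap$kappa)) print(ap$kappa)
  }
  if (!is.null(x$accuracy_part)) {
    cat("quality-accuracy correlations:\n")
    print(x$accuracy_part)
  }
  invisible(x)
}

#' Write a quality report as JSON
#'
#' @param result A `roma_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality_json <- function(result, path) {
  q <- result$quality
  payload <- list(
    record_id = q$record_id,
    self_consistency = q$self_consistency,
    std_width = q$std_width,
    label = q$label,
    cutpoints = list(self_consistency = result$config$sc_cut,
                     std_width = result$config$width_cut),
    n_frames = q$n_frames,
    n_beats = nrow(result$beats)
  )
  if (!is.null(result$agreement)) {
    payload$agreement <- as.list(result$agreement)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
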