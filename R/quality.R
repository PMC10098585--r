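#' Self-consistency signal-quality index
#'
#' The percentage of beat-aligned points at which the time-domain and
#' frequency-domain heart rates agree to within `tol_bpm` (10 BPM by
#' default). Both series must be evaluated at identical times (interpolate
#' the frequency-domain HR to the beat time stamps first); agreement at
#' exactly the tolerance counts (inclusive comparison).
#'
#' @param hr_time Data frame with `time_s`, `hr` (time-domain HR at beats).
#' @param hr_freq Data frame with `time_s`, `hr` (frequency-domain HR at the
#'   same times).
#' @param tol_bpm Agreement tolerance, BPM.
#' @param exclude Optional logical mask of points to drop (outlier beats).
#' @return Self-consistency in percent, \[0, 100\].
#' @export
self_consistency <- function(hr_time, hr_freq, tol_bpm = 10, exclude = NULL) {
  if (nrow(hr_time) != nrow(hr_freq) ||
      max(abs(hr_time$time_s - hr_freq$time_s)) > 1e-8) {
    abort_data("Series must be evaluated at identical times; align first.")
  }
  keep <- !(exclude %||% rep(FALSE, nrow(hr_time)))
  keep <- keep & is.finite(hr_time$hr) & is.finite(hr_freq$hr)
  n <- sum(keep)
  if (n < 1) abort_data("No comparable points after exclusions.")
  100 * sum(abs(hr_time$hr[keep] - hr_freq$hr[keep]) <= tol_bpm) / n
}

#' Standard deviation of the spectral line width
#'
#' The sample standard deviation (n - 1 denominator) of the per-frame
#' spectral line width, in BPM. Impulsive contact-loss artifacts broaden the
#' line intermittently, so a large value signals poor mounting.
#'
#' @param track A `spectral_track` with `line_width` filled in.
#' @return STD-width in BPM.
#' @export
std_width <- function(track) {
  stopifnot(inherits(track, "spectral_track"))
  w <- track$frames$line_width
  if (length(w) < 2 || anyNA(w)) {
    abort_data("Need at least 2 frames with measured line widths.")
  }
  sd(w)
}

#' Classify record quality from the two indices
#'
#' A record is adequate when self-consistency exceeds `sc_cut` AND STD-width
#' is below `width_cut`; it is poor when either index fails. Boundary values
#' classify as poor (strict inequalities).
#'
#' @param sc Self-consistency, percent.
#' @param sw STD-width, BPM.
#' @param sc_cut Self-consistency cut point (default 30).
#' @param width_cut STD-width cut point (default 10 BPM).
#' @return `"adequate"` or `"poor"` (vectorized).
#' @export
classify_quality <- function(sc, sw, sc_cut = 30, width_cut = 10) {
  ifelse(sc > sc_cut & sw < width_cut, "adequate", "poor")
}

#' Quality metrics for one record
#'
#' Convenience wrapper computing both indices and the binary label.
#'
#' @inheritParams self_consistency
#' @param track A `spectral_track` with widths filled in.
#' @param config A [roma_config()].
#' @param record_id Identifier carried into the output.
#' @return One-row tibble: `record_id`, `self_consistency`, `std_width`,
#'   `label`, `n_compared_points`, `n_frames`.
#' @export
quality_metrics <- function(hr_time, hr_freq, track, config = roma_config(),
                            exclude = NULL, record_id = "record") {
  sc <- self_consistency(hr_time, hr_freq, config$sc_tol_bpm, exclude)
  sw <- std_width(track)
  tibble(
    record_id = record_id,
    self_consistency = sc,
    std_width = sw,
    label = classify_quality(sc, sw, config$sc_cut, config$width_cut),
    n_compared_points = sum(!(exclude %||% rep(FALSE, nrow(hr_time)))),
    n_frames = nrow(track$frames)
  )
}

#' ROC analysis and cut-point selection for a quality index
#'
#' Builds the ROC curve of a continuous quality score against binary
#' good/poor labels, treating "poor" as the positive (detected) class. AUC
#' is computed by the trapezoid rule. The chosen threshold maximizes
#' `min(sensitivity, specificity)`; ties are broken by larger Youden's J,
#' then by the smaller threshold.
#'
#' @param scores Numeric quality-index values.
#' @param labels Binary labels: `"good"`/`"poor"`, logical (TRUE = good), or
#'   0/1 (1 = good).
#' @param direction `"higher_is_good"` (e.g. self-consistency) or
#'   `"higher_is_poor"` (e.g. STD-width).
#' @param metric_name Name carried into the result.
#' @return An object of class `roc_cutpoint`: list with `metric_name`,
#'   `threshold`, `sensitivity`, `specificity`, `auc`, and `roc` (tibble of
#'   `threshold`, `fpr`, `tpr`).
#' @export
roc_cutpoint <- function(scores, labels,
                         direction = c("higher_is_good", "higher_is_poor"),
                         metric_name = "score") {
  direction <- match.arg(direction)
  good <- as_good_label(labels)
  if (length(good) != length(scores)) {
    abort_data("`scores` and `labels` must have the same length.")
  }
  if (length(unique(good)) < 2) {
    abort_data("Both quality classes must be present for ROC analysis.")
  }
  # Orient so that larger oriented score = more evidence of POOR signal.
  s <- if (direction == "higher_is_good") -scores else scores
  poor <- !good
  thr <- sort(unique(s))
  cuts <- c(-Inf, thr, Inf) # flag poor when oriented score >= cut
  tpr <- vapply(cuts, function(ct) mean(s[poor] >= ct), numeric(1))
  fpr <- vapply(cuts, function(ct) mean(s[!poor] >= ct), numeric(1))
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
  sens <- tpr
  spec <- 1 - fpr
  score_rule <- pmin(sens, spec)
  j <- sens + spec - 1
  orig_thr <- if (direction == "higher_is_good") -cuts else cuts
  best <- order(-score_rule, -j, orig_thr)[[1]]
  structure(
    list(metric_name = metric_name,
         threshold = orig_thr[[best]],
         sensitivity = sens[[best]],
         specificity = spec[[best]],
         auc = auc,
         roc = tibble(threshold = orig_thr, fpr = fpr, tpr = tpr)),
    class = "roc_cutpoint"
  )
}

as_good_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort_data("Numeric labels must be 0/1.")
    return(labels == 1)
  }
  lab <- tolower(as.character(labels))
  if (!all(lab %in% c("good", "poor", "adequate", "bad"))) {
    abort_data("Labels must be good/poor (or adequate/bad).")
  }
  lab %in% c("good", "adequate")
}

#' @export
print.roc_cutpoint <- function(x, ...) {
  cat(sprintf(
    "<roc_cutpoint '%s'>  AUC = %.3f; threshold = %.4g (sens %.3f, spec %.3f)\n",
    x$metric_name, x$auc, x$threshold, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' @export
tidy.roc_cutpoint <- function(x, ...) x$roc

#' @export
glance.roc_cutpoint <- function(x, ...) {
  tibble(metric_name = x$metric_name, threshold = x$threshold,
         sensitivity = x$sensitivity, specificity = x$specificity,
         auc = x$auc)
}
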