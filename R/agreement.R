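#' Heart-rate agreement metrics against a reference
#'
#' Errors between an estimated HR series and a reference (e.g. ECG
#' telemetry) at aligned time points: RMSE (with a 1/(n-1) denominator by
#' default; set `rmse_denom = "standard"` for 1/n), MAE, mean absolute
#' percent error (normalized by the reference), and accuracy, the percentage
#' of points within `tol_bpm` of the reference (inclusive).
#'
#' @param reference Data frame with `time_s`, `hr` — the criterion HR (> 0).
#' @param estimate Data frame with `time_s`, `hr` at the same times.
#' @param tol_bpm Accuracy tolerance, BPM (default 5).
#' @param exclude Optional logical mask of points to drop (outlier beats).
#' @param rmse_denom `"paper"` (1/(n-1)) or `"standard"` (1/n).
#' @return One-row tibble of class `agreement_stats`: `rmse`, `mae`,
#'   `mae_pct`, `accuracy5`, `n`.
#' @examples
#' ref <- hr_series(c(0, 1), c(100, 110))
#' est <- hr_series(c(0, 1), c(102, 108))
#' error_metrics(ref, est) # rmse 2.83, mae 2, mae_pct 1.91, accuracy5 100
#' @export
error_metrics <- function(reference, estimate, tol_bpm = 5, exclude = NULL,
                          rmse_denom = c("paper", "standard")) {
  rmse_denom <- match.arg(rmse_denom)
  if (nrow(reference) != nrow(estimate) ||
      max(abs(reference$time_s - estimate$time_s)) > 1e-8) {
    abort_data("Series must be evaluated at identical times; align first.")
  }
  keep <- !(exclude %||% rep(FALSE, nrow(reference)))
  keep <- keep & is.finite(reference$hr) & is.finite(estimate$hr)
  x <- reference$hr[keep]
  y <- estimate$hr[keep]
  n <- length(x)
  if (n < 2) abort_data("Need at least 2 comparable points.")
  if (any(x <= 0)) abort_data("Reference HR must be positive (MAE%% divides by it).")
  d <- x - y
  denom <- if (rmse_denom == "paper") n - 1 else n
  out <- tibble(
    rmse = sqrt(sum(d^2) / denom),
    mae = mean(abs(d)),
    mae_pct = 100 * mean(abs(d) / x),
    accuracy5 = 100 * mean(abs(d) <= tol_bpm),
    n = n
  )
  structure(out, class = c("agreement_stats", class(out)))
}

#' Point-biserial correlation
#'
#' Pearson correlation between a binary indicator and a continuous variable;
#' used to associate binary signal-quality labels with continuous error
#' metrics.
#'
#' @param binary 0/1 (or logical) vector; both classes must be present.
#' @param continuous Numeric vector of the same length.
#' @return Correlation in \[-1, 1\].
#' @export
point_biserial <- function(binary, continuous) {
  b <- as.numeric(binary)
  if (length(b) != length(continuous)) {
    abort_data("Inputs must have the same length.")
  }
  if (length(unique(b)) < 2) {
    abort_data("Both classes must be present in `binary`.")
  }
  cor(b, continuous)
}

# Fisher-z confidence interval for a Pearson correlation. (Reported where a
# credible interval would otherwise appear; labelled as a confidence
# interval in all outputs.)
cor_fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the marginal products, plus the Landis-Koch
#' interpretation band. When both raters are constant and identical
#' (`p_e = 1`), kappa is defined as 1 with a warning.
#'
#' @param labels_a,labels_b Binary label vectors of equal length (logical,
#'   0/1, or two-level character).
#' @return A list of class `cohen_kappa`: `kappa`, `p_observed`,
#'   `p_expected`, `band`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 1) {
    abort_data("Label vectors must be non-empty and of equal length.")
  }
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  lev <- sort(unique(c(a, b)))
  if (length(lev) > 2) abort_data("Labels must be binary.")
  po <- mean(a == b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (pe >= 1) {
    warn("Both raters are constant and identical; kappa defined as 1.")
    k <- 1
  } else {
    k <- (po - pe) / (1 - pe)
  }
  structure(list(kappa = k, p_observed = po, p_expected = pe,
                 band = landis_koch(k)),
            class = "cohen_kappa")
}

#' Landis-Koch interpretation of a kappa value
#'
#' @param kappa Kappa value.
#' @return Interpretation string: poor (<= 0), slight (0.01-0.20), fair
#'   (0.21-0.40), moderate (0.41-0.60), substantial (0.61-0.80), almost
#'   perfect (0.81-1.00) agreement.
#' @export
landis_koch <- function(kappa) {
  if (kappa <= 0) "poor agreement"
  else if (kappa <= 0.20) "slight agreement"
  else if (kappa <= 0.40) "fair agreement"
  else if (kappa <= 0.60) "moderate agreement"
  else if (kappa <= 0.80) "substantial agreement"
  else "almost perfect agreement"
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s)\n", x$kappa, x$band))
  invisible(x)
}

#' @export
glance.cohen_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, p_observed = x$p_observed,
         p_expected = x$p_expected, band = x$band)
}

#' Welch's unequal-variance two-sample t test
#'
#' Thin wrapper returning the t statistic and two-sided p value, for
#' comparing error metrics between quality groups.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return A tibble with `t`, `p`, `df`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort_data("Each group needs at least 2 observations.")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    abort_data("Both groups have zero variance; t statistic undefined.")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter))
}
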