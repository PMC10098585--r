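test_that("self-consistency counts agreements within tolerance, inclusively", {
  tt <- tibble::tibble(time_s = 1:3, hr = c(80, 80, 100))
  ff <- tibble::tibble(time_s = 1:3, hr = c(85, 95, 100))
  expect_equal(self_consistency(tt, ff), 100 * 2 / 3)

  expect_equal(self_consistency(tt, tt), 100)

  exact10 <- tibble::tibble(time_s = 1:3, hr = c(90, 90, 110))
  expect_equal(self_consistency(tt, exact10), 100) # <= is inclusive

  shifted <- function(df, k) dplyr::mutate(df, hr = hr + k)
  expect_equal(self_consistency(shifted(tt, 17), shifted(ff, 17)),
               self_consistency(tt, ff))

  misaligned <- tibble::tibble(time_s = c(1, 2, 3.5), hr = c(85, 95, 100))
  expect_error(self_consistency(tt, misaligned), class = "romahr_data_error")

  # excluded (outlier) beats do not enter the count
  expect_equal(self_consistency(tt, ff, exclude = c(FALSE, TRUE, FALSE)), 100)
})

test_that("std_width is the sample standard deviation of frame widths", {
  mk <- function(w) {
    tr <- compute_spectrogram(sin(2 * pi * 1.2 * (0:5000) / 46.3), 46.3,
                              window_s = 30, hop_s = 30)
    tr$frames <- tibble::tibble(frame = seq_along(w), time_s = seq_along(w),
                                peak_hr = 70, line_width = w)
    tr
  }
  expect_equal(std_width(mk(rep(5, 4))), 0)
  expect_equal(std_width(mk(c(4, 6))), sqrt(2), tolerance = 1e-12)
  expect_error(std_width(mk(5)), class = "romahr_data_error")

  tone <- track_peak_and_width(
    compute_spectrogram(tone_record(1.2)$ppg, 46.3)
  )
  expect_lt(std_width(tone), 1)
})

test_that("quality classification uses strict cut-point inequalities", {
  expect_equal(classify_quality(98.26, 3.05), "adequate")
  expect_equal(classify_quality(12.05, 12.82), "poor")
  expect_equal(classify_quality(30, 10), "poor")   # boundaries are poor
  expect_equal(classify_quality(30.01, 9.99), "adequate")
  expect_equal(classify_quality(c(50, 20), c(5, 5)), c("adequate", "poor"))
})

test_that("ROC cut-point selection separates classes and flips with direction", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c("poor", "poor", "poor", "good", "good", "good")
  r <- roc_cutpoint(scores, labels, "higher_is_good")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # "adequate iff score > threshold": any threshold in [3, 10) separates
  expect_gte(r$threshold, 3)
  expect_lt(r$threshold, 10)

  r2 <- roc_cutpoint(scores, labels, "higher_is_poor")
  expect_equal(r2$auc, 0)

  expect_error(roc_cutpoint(1:5, rep("good", 5)), class = "romahr_data_error")
})

test_that("ROC AUC is near 0.5 when labels are independent of scores", {
  set.seed(77)
  scores <- rnorm(200)
  labels <- sample(c("good", "poor"), 200, replace = TRUE)
  r <- roc_cutpoint(scores, labels, "higher_is_good")
  expect_lt(abs(r$auc - 0.5), 0.08)
})

test_that("trapezoid AUC equals the brute-force pair-counting oracle", {
  auc_pairs <- function(scores, good, direction) {
    s <- if (direction == "higher_is_good") -scores else scores
    pos <- s[!good]; neg <- s[good] # positive class = poor
    gr <- outer(pos, neg, ">"); eq <- outer(pos, neg, "==")
    (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
  }
  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(0:2, 1)) # ties likely
    good <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(good)) < 2) next
    dir <- sample(c("higher_is_good", "higher_is_poor"), 1)
    expect_equal(roc_cutpoint(scores, good, dir)$auc,
                 auc_pairs(scores, good, dir), tolerance = 1e-10)
  }
})

test_that("clean synthetic records classify adequate at the default cuts", {
  syn <- quick_synth(hr = 80, duration_s = 240, seed = 101)
  res <- roma_process(syn$record)
  expect_gte(res$quality$self_consistency, 90)
  expect_lt(res$quality$std_width, 10)
  expect_equal(res$quality$label, "adequate")
})
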