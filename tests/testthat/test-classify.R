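test_that("peak positions mark the starts of new matches", {
  expect_identical(find_peaks(integer(0)), integer(0))
  expect_identical(find_peaks(c(5L)), 1L)
  # strictly decreasing: only the first position is a peak
  expect_identical(find_peaks(c(5L, 4L, 3L, 2L, 1L)), 1L)
  # equal or rising values start new matches
  expect_identical(find_peaks(c(3L, 2L, 2L, 5L, 4L)), c(1L, 3L, 4L))
  expect_identical(find_peaks(c(0L, 0L, 1L)), c(1L, 2L, 3L))
})

test_that("substring complexity separates repetitive from random shreds", {
  # constant sequence: 1 distinct k-mer for every k, delta = max 1/1 = 1
  expect_equal(shred_complexity(bin_seq(rep(2L, 50), 6)), 1)
  # period-2 sequence: at k = 2 there are 2 distinct, delta = max(2/1, 2/2,
  # 2/3...) = 2
  expect_equal(shred_complexity(bin_seq(rep(c(0L, 1L), 25), 6)), 2)
  set.seed(51)
  rnd <- bin_seq(sample(0:5, 200, replace = TRUE), 6)
  expect_gt(shred_complexity(rnd), shred_complexity(bin_seq(rep(c(0L, 1L),
                                                               100), 6)))
  # entropy: uniform alphabet -> log2(n_bins) bits, constant -> 0
  expect_equal(shred_complexity(bin_seq(rep(0:3, 25), 4), method = "entropy"),
               2)
  expect_equal(shred_complexity(bin_seq(rep(1L, 9), 4), method = "entropy"),
               0)
  expect_error(shred_complexity(bin_seq(integer(0), 6)), "empty")
})

# minimal index skeleton for vote tests: 3 shreds, 2 classes
vote_index <- function(C_d = c(1, 1, 1),
                       polarity = c("positive", "null")) {
  list(shreds = data.frame(shred_id = 0:2, class_id = c(0L, 0L, 1L),
                           C_d = C_d),
       class_table = data.frame(class_id = 0:1,
                                class_name = c("pos", "neg"),
                                polarity = polarity,
                                stringsAsFactors = FALSE))
}

test_that("vote scores aggregate peak lengths per shred with weights", {
  idx <- vote_index(C_d = c(0.5, 1, 0.25))
  prof <- sigclass:::new_pml_profile(
    P = c(4L, 3L, 5L, 4L, 4L, 0L),
    D = c(0L, 0L, 2L, 2L, 0L, 1L),
    "r", c(0L))
  # peaks: positions 1 (always), 3 (5 >= 3), 5 (4 >= 4)
  cfg <- classification_config(complexity_correction = FALSE)
  s <- score_documents(prof, idx, cfg)
  expect_equal(as.vector(s), c(4 + 4, 0, 5), ignore_attr = TRUE)
  expect_equal(attr(s, "n_peaks"), 3L)
  s2 <- score_documents(prof, idx, classification_config())
  expect_equal(as.vector(s2), c(8 * 0.5, 0, 5 * 0.25), ignore_attr = TRUE)
})

test_that("multi-class decisions pick the argmax shred with tie flags", {
  idx <- vote_index()
  mk <- function(v) {
    s <- stats::setNames(v, 0:2)
    attr(s, "n_peaks") <- 2L
    s
  }
  row <- classify_multiclass(mk(c(3, 1, 7)), idx, read_id = "r1")
  expect_equal(row$predicted_class, "neg")
  expect_equal(row$top_shred, 2L)
  expect_equal(row$top_score, 7)
  expect_equal(row$flags, "")
  tie <- classify_multiclass(mk(c(7, 1, 7)), idx)
  expect_equal(tie$top_shred, 0L)  # lowest shred id wins ties
  expect_match(tie$flags, "tie")
  zero <- classify_multiclass(mk(c(0, 0, 0)), idx)
  expect_match(zero$flags, "zero_signal")
})

test_that("binary decisions threshold the spike ratio strictly", {
  idx <- vote_index()
  mk <- function(v) stats::setNames(v, 0:2)
  cfg <- classification_config(spike_ratio_threshold = 1.0)
  # ratio 6/3 = 2 > 1: positive
  pos <- classify_binary(mk(c(6, 2, 3)), idx, cfg)
  expect_equal(pos$predicted_class, "pos")
  expect_equal(pos$spike_ratio, 2)
  expect_equal(pos$null_score, 3)
  # ratio exactly at the threshold is NOT positive (strict >)
  eq <- classify_binary(mk(c(3, 2, 3)), idx, cfg)
  expect_equal(eq$predicted_class, "neg")
  # zero null score with positive signal: infinite ratio, positive
  inf <- classify_binary(mk(c(4, 1, 0)), idx, cfg)
  expect_equal(inf$spike_ratio, Inf)
  expect_equal(inf$predicted_class, "pos")
  # all zero: flagged null call
  zz <- classify_binary(mk(c(0, 0, 0)), idx, cfg)
  expect_equal(zz$predicted_class, "neg")
  expect_match(zz$flags, "zero_signal")
  # an index without both polarities cannot run binary mode
  expect_error(
    classify_binary(mk(c(1, 1, 1)), vote_index(polarity = c("plain",
                                                            "plain"))),
    "positive and one null")
})

test_that("threshold calibration follows the midpoint convention", {
  set.seed(52)
  ratios <- sort(runif(100, 0.1, 5), decreasing = TRUE)
  # expecting 30% positive: threshold between the 30th and 31st largest
  thr <- calibrate_threshold(ratios, 0.3)
  expect_equal(thr, (ratios[30] + ratios[31]) / 2)
  expect_equal(sum(ratios > thr), 30L)
  expect_equal(calibrate_threshold(ratios, 1), min(ratios))
  expect_equal(calibrate_threshold(ratios, 0), max(ratios))
  expect_error(calibrate_threshold(ratios[1:10], 0.5), "at least 50")
  expect_warning(calibrate_threshold(rep(2, 60), 0.5), "degenerate")
  # data.frame input and non-finite filtering
  df <- data.frame(spike_ratio = c(ratios, Inf, NA))
  expect_equal(calibrate_threshold(df, 0.3), thr)
})

test_that("classification configs validate their inputs", {
  expect_error(classification_config(spike_ratio_threshold = 0), "> 0")
  cfg <- classification_config(2.5, FALSE)
  expect_equal(cfg$spike_ratio_threshold, 2.5)
  expect_false(cfg$complexity_correction)
})
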