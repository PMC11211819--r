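#' Classification configuration
#'
#' @param spike_ratio_threshold binary decision threshold on the ratio of the
#'   top positive-class shred score to the top null-class shred score; a read
#'   is called positive iff the ratio is strictly greater. The default 1.0
#'   suits mixtures with roughly equal class proportions; for skewed
#'   mixtures calibrate with [calibrate_threshold()].
#' @param complexity_correction weight each shred's votes by its normalized
#'   sequence complexity, down-weighting matches to low-complexity regions
#'   (default on).
#' @return a list of class `classification_config`.
#' @export
classification_config <- function(spike_ratio_threshold = 1.0,
                                  complexity_correction = TRUE) {
  if (spike_ratio_threshold <= 0) stop("spike_ratio_threshold must be > 0")
  structure(list(spike_ratio_threshold = spike_ratio_threshold,
                 complexity_correction = isTRUE(complexity_correction)),
            class = "classification_config")
}

#' Peak positions of a PML vector
#'
#' Within one exact match the pseudo-matching length decrements by 1 per
#' position, so any position where it fails to decrease starts a new match.
#' Position 1 is always a peak (the first match must be representable);
#' position `i >= 2` is a peak iff `P[i] >= P[i-1]`. Using only peaks in the
#' vote prevents long matches from being counted once per position.
#'
#' @param P integer PML vector.
#' @return integer vector of 1-based peak positions (empty for empty input).
#' @export
find_peaks <- function(P) {
  if (length(P) == 0L) return(integer())
  which(c(TRUE, diff(P) >= 0L))
}

#' Sequence complexity of a shred
#'
#' `"delta"`: substring complexity, the maximum over `k` of the number of
#' distinct length-`k` substrings divided by `k`; `k` is capped (default 12)
#' since the maximizing `k` for small alphabets occurs early and the cap
#' keeps index building linear. `"entropy"`: order-0 empirical entropy in
#' bits. Low-complexity (repetitive) shreds score lower than random shreds
#' of the same length; [build_index()] normalizes the values across the
#' collection to (0, 1] to obtain the vote weights.
#'
#' @param bins a `bin_seq`.
#' @param max_k cap on substring length for `"delta"`.
#' @param method complexity measure.
#' @return a single non-negative number.
#' @export
shred_complexity <- function(bins, max_k = 12L,
                             method = c("delta", "entropy")) {
  method <- match.arg(method)
  s <- bins$symbols
  L <- length(s)
  if (L == 0L) stop("empty shred")
  if (method == "entropy") {
    p <- tabulate(s + 1L, nbins = bins$n_bins) / L
    p <- p[p > 0]
    return(-sum(p * log2(p)))
  }
  str <- encode_ascii(bins)
  best <- 0
  for (k in seq_len(min(max_k, L))) {
    nk <- length(unique(substring(str, seq_len(L - k + 1L),
                                  k:L)))
    best <- max(best, nk / k)
  }
  best
}

#' Weighted per-shred vote scores
#'
#' Evaluates the peak-weighted plurality vote: each peak position `i`
#' contributes `P[i]` votes to shred `D[i]`, scaled by the shred's
#' complexity weight when the correction is on:
#' `score(d) = sum over peaks i with D[i] = d of P[i] * C_d`.
#'
#' @param profile a `pml_profile`.
#' @param index the `ref_index` the profile was computed against.
#' @param cfg a [classification_config()].
#' @return named numeric vector of scores, one per shred id (names are
#'   shred ids), in shred-id order.
#' @export
score_documents <- function(profile, index,
                            cfg = classification_config()) {
  ids <- index$shreds$shred_id
  scores <- stats::setNames(numeric(length(ids)), ids)
  pk <- find_peaks(profile$P)
  pk <- pk[profile$P[pk] > 0L]
  if (length(pk) > 0L) {
    agg <- tapply(as.numeric(profile$P[pk]), profile$D[pk], sum)
    scores[match(as.integer(names(agg)), ids)] <- as.numeric(agg)
    if (cfg$complexity_correction) {
      scores <- scores * index$shreds$C_d
    }
  }
  attr(scores, "n_peaks") <- length(pk)
  scores
}

top_shred_score <- function(scores, ids, subset) {
  if (!any(subset)) return(list(score = NA_real_, shred = NA_integer_))
  sub_scores <- scores[subset]
  sub_ids <- ids[subset]
  j <- which.max(sub_scores)  # first maximum = lowest shred id (ids sorted)
  list(score = unname(sub_scores[j]), shred = sub_ids[j])
}

#' Multi-class decision from vote scores
#'
#' The winning shred is the argmax of the scores (ties broken toward the
#' lowest shred id and flagged); the predicted class is the winning shred's
#' class. Every read receives a label; reads whose scores are all zero are
#' flagged `zero_signal`.
#'
#' @param scores output of [score_documents()].
#' @param index the `ref_index`.
#' @param read_id identifier carried into the result.
#' @return a one-row data.frame: `read_id`, `predicted_class`, `top_shred`,
#'   `top_score`, `null_score` (NA here), `spike_ratio` (NA here),
#'   `n_peaks`, `flags`.
#' @export
classify_multiclass <- function(scores, index, read_id = "read") {
  ids <- index$shreds$shred_id
  flags <- character()
  j <- which.max(scores)
  if (sum(scores == scores[j]) > 1L) flags <- c(flags, "tie")
  if (scores[j] == 0) flags <- c(flags, "zero_signal")
  cls <- index$class_table$class_name[
    match(index$shreds$class_id[j], index$class_table$class_id)]
  data.frame(read_id = read_id, predicted_class = cls,
             top_shred = ids[j], top_score = unname(scores[j]),
             null_score = NA_real_, spike_ratio = NA_real_,
             n_peaks = attr(scores, "n_peaks") %||% NA_integer_,
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Binary (positive versus null) decision from vote scores
#'
#' Compares the best-scoring shred of the positive class(es) with the best
#' of the null class(es): the spike ratio is their quotient, and the read is
#' called positive iff the ratio is strictly greater than the configured
#' threshold. A zero null score with a positive top score is an infinite
#' ratio (positive call); both zero yields a flagged null call.
#'
#' @param scores output of [score_documents()].
#' @param index the `ref_index`; its class table must mark at least one
#'   `positive` and one `null` class.
#' @param cfg a [classification_config()].
#' @param read_id identifier carried into the result.
#' @return a one-row data.frame (same columns as [classify_multiclass()]).
#' @export
classify_binary <- function(scores, index,
                            cfg = classification_config(),
                            read_id = "read") {
  ct <- index$class_table
  pos_cls <- ct$class_id[ct$polarity == "positive"]
  nul_cls <- ct$class_id[ct$polarity == "null"]
  if (length(pos_cls) == 0L || length(nul_cls) == 0L) {
    stop("binary mode needs at least one positive and one null class")
  }
  ids <- index$shreds$shred_id
  pos <- top_shred_score(scores, ids, index$shreds$class_id %in% pos_cls)
  nul <- top_shred_score(scores, ids, index$shreds$class_id %in% nul_cls)
  flags <- character()
  if (nul$score > 0) {
    ratio <- pos$score / nul$score
  } else if (pos$score > 0) {
    ratio <- Inf
  } else {
    ratio <- NA_real_
    flags <- c(flags, "zero_signal")
  }
  positive <- !is.na(ratio) && ratio > cfg$spike_ratio_threshold
  cls_id <- if (positive) pos_cls[1L] else nul_cls[1L]
  top <- if (positive) pos else nul
  # report the winning side's best shred class, not just the polarity group
  if (!is.na(top$shred)) {
    cls_id <- index$shreds$class_id[match(top$shred, ids)]
  }
  data.frame(read_id = read_id,
             predicted_class = ct$class_name[match(cls_id, ct$class_id)],
             top_shred = top$shred, top_score = pos$score,
             null_score = nul$score, spike_ratio = ratio,
             n_peaks = attr(scores, "n_peaks") %||% NA_integer_,
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the spike-ratio threshold from burn-in reads
#'
#' Given spike ratios observed during a burn-in period and the expected
#' fraction of positive reads, returns the threshold whose strict-greater
#' rule calls that fraction positive. Convention: with
#' `m = round(fraction * n)` reads to be called positive, the threshold is
#' the midpoint between the m-th and (m+1)-th largest ratio; `fraction = 1`
#' returns the minimum ratio.
#'
#' @param ratios numeric spike ratios from at least 50 burn-in reads (or a
#'   list/data.frame of classification results with a `spike_ratio` column).
#' @param expected_positive_fraction expected proportion of positive reads.
#' @return the calibrated threshold.
#' @export
calibrate_threshold <- function(ratios, expected_positive_fraction) {
  if (is.data.frame(ratios)) ratios <- ratios$spike_ratio
  ratios <- ratios[is.finite(ratios)]
  n <- length(ratios)
  if (n < 50L) stop("need at least 50 burn-in reads with finite ratios")
  f <- expected_positive_fraction
  if (f < 0 || f > 1) stop("expected_positive_fraction must be in [0, 1]")
  srt <- sort(ratios, decreasing = TRUE)
  if (length(unique(srt)) == 1L) {
    warning("degenerate burn-in: all spike ratios equal")
    return(srt[1L])
  }
  m <- round(f * n)
  if (m >= n) return(srt[n])
  if (m <= 0L) return(srt[1L])
  (srt[m] + srt[m + 1L]) / 2
}
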