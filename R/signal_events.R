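#' Event detection parameters
#'
#' Parameters of the rolling Welch t-test segmenter. Two t-statistic traces
#' are computed (a short and a long window); boundaries are placed at local
#' maxima exceeding the per-trace threshold, with the short trace masking the
#' long one Scrappie-style. Defaults follow the constants commonly used for
#' R9.4 signal segmentation (windows 3/6 samples, thresholds
#' 4.30265/2.57058, peak height 1.0), chosen to balance stay and skip
#' errors; all are overridable.
#'
#' @param window_short,window_long rolling window lengths in samples;
#'   `window_short < window_long`.
#' @param tstat_threshold_short,tstat_threshold_long minimum t-statistic for
#'   a boundary in each trace.
#' @param peak_height minimum prominence of a t-statistic peak.
#' @param var_floor variance floor applied per window so noiseless plateaus
#'   yield finite statistics.
#' @return a list of class `event_detection_params`.
#' @export
event_detection_params <- function(window_short = 3L, window_long = 6L,
                                   tstat_threshold_short = 4.30265,
                                   tstat_threshold_long = 2.57058,
                                   peak_height = 1.0,
                                   var_floor = 1e-8) {
  if (window_short >= window_long) stop("window_short must be < window_long")
  if (tstat_threshold_short <= 0 || tstat_threshold_long <= 0) {
    stop("t-statistic thresholds must be positive")
  }
  structure(list(window_short = as.integer(window_short),
                 window_long = as.integer(window_long),
                 tstat_threshold_short = tstat_threshold_short,
                 tstat_threshold_long = tstat_threshold_long,
                 peak_height = peak_height,
                 var_floor = var_floor),
            class = "event_detection_params")
}

new_event_seq <- function(means, dwells, starts, low_confidence = FALSE) {
  structure(list(means = as.numeric(means), dwells = as.integer(dwells),
                 starts = as.integer(starts),
                 low_confidence = low_confidence),
            class = "event_seq")
}

#' Segment raw current into events
#'
#' Groups consecutive current samples into events, each corresponding
#' (roughly) to one nucleotide dwelling in the pore, by cutting at
#' significant level changes found with two rolling Welch t-tests. Every
#' sample belongs to exactly one event; the event mean is the arithmetic
#' mean of its samples.
#'
#' @param samples numeric vector of current measurements (pA).
#' @param params an [event_detection_params()] object.
#' @return an `event_seq` with fields `means`, `dwells`, `starts`
#'   (0-based sample offsets) and a `low_confidence` flag set when the
#'   signal was shorter than the long window.
#' @export
detect_events <- function(samples, params = event_detection_params()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty signal")
  if (any(!is.finite(samples))) stop("signal contains non-finite samples")
  n <- length(samples)
  if (n < params$window_long) {
    return(new_event_seq(mean(samples), n, 0L, low_confidence = TRUE))
  }
  bnd <- detect_boundaries_cpp(samples, params$window_short,
                               params$window_long,
                               params$tstat_threshold_short,
                               params$tstat_threshold_long,
                               params$peak_height, params$var_floor)
  bnd <- bnd[bnd > 0L & bnd < n]
  starts <- c(0L, bnd)
  ends <- c(bnd, n)
  dwells <- ends - starts
  csum <- c(0, cumsum(samples))
  means <- (csum[ends + 1L] - csum[starts + 1L]) / dwells
  new_event_seq(means, dwells, starts)
}

# --- Welford / Chan running statistics -------------------------------------

welford_init <- function() {
  list(n = 0L, mean = 0, M2 = 0)
}

# merge a weighted batch of values into the running state (parallel-merge
# form, exact associativity up to float rounding); w defaults to unit weights
welford_merge <- function(state, x, w = NULL) {
  if (length(x) == 0L) return(state)
  if (is.null(w)) w <- rep(1, length(x))
  nb <- sum(w)
  mb <- sum(w * x) / nb
  M2b <- sum(w * (x - mb)^2)
  if (state$n == 0) return(list(n = nb, mean = mb, M2 = M2b))
  n <- state$n + nb
  delta <- mb - state$mean
  list(n = n,
       mean = state$mean + delta * nb / n,
       M2 = state$M2 + M2b + delta^2 * state$n * nb / n)
}

welford_sd <- function(state) {
  if (state$n == 0) return(NA_real_)
  sqrt(state$M2 / state$n)  # population convention
}

#' Normalize event means onto the pore-model scale
#'
#' Shifts and scales event means so the read's signal distribution matches
#' the pore model's global distribution:
#' `norm(e) = (e - mu_read) / sd_read * model_std + model_mean`.
#' `mu_read`/`sd_read` (population convention) are computed over event means
#' *weighted by event dwell*, i.e. they are the statistics of the denoised
#' staircase signal in the sample domain. Duration weighting makes the
#' statistics invariant to how a constant stretch is segmented into events,
#' so over- or under-segmentation of plateaus does not perturb the scale.
#' State is maintained incrementally via weighted Welford/Chan merging so
#' successive chunks of one read update a shared state; the supplied events
#' are normalized with the statistics *after* folding them in, so a single
#' whole-read call is an exact batch computation. Normalization is strictly
#' per read; statistics are never shared across reads.
#'
#' @param events an `event_seq`.
#' @param model a `pore_model` (or any list with `model_mean`, `model_std`).
#' @param state running statistics from a previous chunk of the same read,
#'   or `NULL` to start fresh.
#' @return list with `events` (normalized `event_seq`) and `state` (updated
#'   running statistics).
#' @export
normalize_events <- function(events, model, state = NULL) {
  if (length(events$means) == 0L) stop("no events to normalize")
  if (is.null(state)) state <- welford_init()
  state <- welford_merge(state, events$means, w = events$dwells)
  s <- welford_sd(state)
  if (s == 0) {
    warning("constant read: zero variance, mapping all events to model_mean")
    norm <- rep(model$model_mean, length(events$means))
  } else {
    norm <- (events$means - state$mean) / s * model$model_std +
      model$model_mean
  }
  out <- events
  out$means <- norm
  list(events = out, state = state)
}

# --- signal TSV container ---------------------------------------------------

#' Read a signal TSV
#'
#' One read per line: `read_id<TAB>comma-separated floats`.
#'
#' @param path file path.
#' @return named list of numeric sample vectors.
#' @export
read_signal_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("malformed signal TSV at line ", bad[1L])
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  vals <- lapply(parts, function(p) {
    v <- as.numeric(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
    if (any(is.na(v))) stop("non-numeric sample for read ", p[[1L]])
    v
  })
  stats::setNames(vals, ids)
}

#' Write a signal TSV
#'
#' @param reads named list of numeric sample vectors.
#' @param path output path.
#' @export
write_signal_tsv <- function(reads, path) {
  lines <- vapply(seq_along(reads), function(i) {
    paste0(names(reads)[i], "\t",
           paste(sprintf("%.5f", reads[[i]]), collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Split a sample vector into fixed-size chunks
#'
#' A chunk is roughly one second of sequencing (about 4000 samples).
#'
#' @param samples numeric vector.
#' @param chunk_size samples per chunk.
#' @return list of numeric vectors whose concatenation is `samples`.
#' @export
signal_chunks <- function(samples, chunk_size = 4000L) {
  n <- length(samples)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = chunk_size)
  lapply(starts, function(s) samples[s:min(n, s + chunk_size - 1L)])
}

#' @export
print.event_seq <- function(x, ...) {
  cat(sprintf("event_seq: %d events over %d samples (mean dwell %.1f)\n",
              length(x$means), sum(x$dwells), mean(x$dwells)))
  invisible(x)
}
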