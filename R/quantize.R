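#' Binning configuration
#'
#' The picoamp range of the pore model, `[min_p, max_p]`, is divided into
#' `n_bins` equal-width bins of width `s_p = (max_p - min_p) / n_bins`.
#' Values below `min_p` clamp to bin 0 and values above `max_p` to bin
#' `n_bins - 1`. Six bins is the default alphabet size, wide enough to
#' absorb amplitude noise while keeping exact matches specific.
#'
#' @param model optional `pore_model` supplying `min_p`/`max_p`.
#' @param n_bins alphabet size (>= 2).
#' @param min_p,max_p explicit range bounds (pA) when no model is given.
#' @return a list of class `binning_config` with `n_bins`, `min_p`, `max_p`,
#'   `s_p`.
#' @export
binning_config <- function(model = NULL, n_bins = 6L, min_p = NULL,
                           max_p = NULL) {
  if (!is.null(model)) {
    min_p <- model$min_p
    max_p <- model$max_p
  }
  if (is.null(min_p) || is.null(max_p)) {
    stop("supply either a pore model or explicit min_p/max_p")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  s_p <- (max_p - min_p) / n_bins
  if (!is.finite(s_p) || s_p <= 0) stop("bin width must be positive")
  structure(list(n_bins = n_bins, min_p = min_p, max_p = max_p, s_p = s_p),
            class = "binning_config")
}

#' Quantize current values into picoamp bins
#'
#' Vectorized, total and monotone on finite inputs: 0 below the range,
#' `n_bins - 1` above it, otherwise `floor((e_c - min_p) / s_p)` with the top
#' boundary `e_c == max_p` clamped into the last bin (bins are half-open
#' except the closed top bin).
#'
#' @param e_c numeric vector of current values (pA).
#' @param cfg a [binning_config()].
#' @return integer vector of bin indices in `0:(n_bins - 1)`.
#' @export
bin_value <- function(e_c, cfg) {
  if (any(!is.finite(e_c))) stop("bin_value requires finite inputs")
  b <- floor((e_c - cfg$min_p) / cfg$s_p)
  b[e_c < cfg$min_p] <- 0
  b[e_c > cfg$max_p] <- cfg$n_bins - 1L
  as.integer(pmin(b, cfg$n_bins - 1L))
}

#' Bin-sequence constructor
#'
#' A bin sequence is a string over the alphabet `{0, ..., n_bins - 1}` of
#' picoamp-range symbols, optionally homopolymer compressed.
#'
#' @param symbols integer vector of symbols in `0:(n_bins - 1)`.
#' @param n_bins alphabet size.
#' @param hpc whether the sequence is homopolymer compressed.
#' @param source `"read"` or `"reference"`.
#' @return an object of class `bin_seq`.
#' @export
bin_seq <- function(symbols, n_bins, hpc = FALSE, source = "read") {
  symbols <- as.integer(symbols)
  if (length(symbols) > 0L &&
      (min(symbols) < 0L || max(symbols) >= n_bins)) {
    stop("symbols out of range for n_bins = ", n_bins)
  }
  if (hpc && length(symbols) > 1L && any(diff(symbols) == 0L)) {
    stop("hpc bin_seq must not contain equal adjacent symbols")
  }
  structure(list(symbols = symbols, n_bins = as.integer(n_bins),
                 hpc = hpc, source = source),
            class = "bin_seq")
}

#' Quantize normalized events
#'
#' Applies [bin_value()] to the event means. Dwell times are carried by the
#' event sequence for diagnostics but play no role in binning.
#'
#' @param events a (normalized) `event_seq`.
#' @param cfg a [binning_config()].
#' @return an uncompressed `bin_seq` with `source = "read"`.
#' @export
bin_events <- function(events, cfg) {
  bin_seq(bin_value(events$means, cfg), cfg$n_bins, hpc = FALSE,
          source = "read")
}

#' Homopolymer-compress a bin sequence
#'
#' Collapses each maximal run of identical symbols to a single symbol.
#' Stay errors (one k-mer split over several events) appear as runs of one
#' symbol, so compressing the read -- and the reference, so true repeats
#' stay queryable -- absorbs them. Idempotent; never increases length.
#'
#' @param bins a `bin_seq`.
#' @return a `bin_seq` with `hpc = TRUE`.
#' @export
hpc_compress <- function(bins) {
  s <- bins$symbols
  if (length(s) > 1L) {
    s <- s[c(TRUE, diff(s) != 0L)]
  }
  bin_seq(s, bins$n_bins, hpc = TRUE, source = bins$source)
}

#' Project a reference sequence into the bin alphabet
#'
#' Walks the k-mers of `seq` through the pore model to get the expected
#' current trace, standardizes the trace onto the model's global scale (the
#' same affine family applied to reads by [normalize_events()]; see the
#' methods vignette), quantizes with [bin_value()], and homopolymer
#' compresses. Both the read and the reference pipeline end in HPC so their
#' outputs live in the same space.
#'
#' @param seq nucleotide string (ACGT; split at ambiguity codes first).
#' @param model a `pore_model`.
#' @param cfg a [binning_config()].
#' @param standardize standardize the expected trace onto
#'   (`model_mean`, `model_std`) before binning (default). `FALSE` bins the
#'   raw expected levels.
#' @param hpc homopolymer-compress the result (default).
#' @return a `bin_seq` with `source = "reference"`.
#' @export
reference_to_binseq <- function(seq, model, cfg, standardize = TRUE,
                                hpc = TRUE) {
  lv <- expected_signal(model, seq)
  if (standardize) {
    s <- pop_sd(lv)
    if (s == 0) {
      lv <- rep(model$model_mean, length(lv))
    } else {
      lv <- (lv - mean(lv)) / s * model$model_std + model$model_mean
    }
  }
  out <- bin_seq(bin_value(lv, cfg), cfg$n_bins, hpc = FALSE,
                 source = "reference")
  if (hpc) hpc_compress(out) else out
}

# printable characters for the bin alphabet: digits then upper then lower
ASCII_ALPHABET <- c(as.character(0:9), LETTERS, letters)

#' Encode a bin sequence as printable ASCII
#'
#' Bin `i` maps to `'0' + i` for `i < 10`, then letters; supports alphabets
#' up to size 62. [decode_ascii()] is the exact inverse.
#'
#' @param bins a `bin_seq`.
#' @return a single string.
#' @export
encode_ascii <- function(bins) {
  if (bins$n_bins > 62L) stop("ASCII encoding supports at most 62 bins")
  paste(ASCII_ALPHABET[bins$symbols + 1L], collapse = "")
}

#' Decode an ASCII-encoded bin sequence
#'
#' @param chars a single string produced by [encode_ascii()].
#' @param n_bins alphabet size; characters outside the first `n_bins`
#'   alphabet characters are an error.
#' @param hpc,source metadata for the reconstructed `bin_seq`.
#' @return a `bin_seq`.
#' @export
decode_ascii <- function(chars, n_bins, hpc = FALSE, source = "read") {
  if (nchar(chars) == 0L) return(bin_seq(integer(), n_bins, hpc, source))
  cc <- strsplit(chars, "", fixed = TRUE)[[1L]]
  idx <- match(cc, ASCII_ALPHABET[seq_len(n_bins)])
  if (any(is.na(idx))) {
    stop("invalid symbol character(s) for n_bins = ", n_bins, ": ",
         paste(unique(cc[is.na(idx)]), collapse = ", "))
  }
  bin_seq(idx - 1L, n_bins, hpc = hpc, source = source)
}

#' @export
print.bin_seq <- function(x, ...) {
  head_str <- paste(utils::head(x$symbols, 30L), collapse = "")
  cat(sprintf("bin_seq (%s%s): %d symbols over alphabet %d [%s%s]\n",
              x$source, if (x$hpc) ", hpc" else "", length(x$symbols),
              x$n_bins, head_str,
              if (length(x$symbols) > 30L) "..." else ""))
  invisible(x)
}
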