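#' @useDynLib sigclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' All k-mers over ACGT in lexicographic order
#' @noRd
all_kmers <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; flip for lexicographic order
  sort(apply(grid, 1L, paste, collapse = ""))
}

# population (divide-by-N) standard deviation, the convention used throughout
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

new_pore_model <- function(k, levels) {
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    stop("pore model levels must be finite and positive")
  }
  min_p <- min(levels)
  max_p <- max(levels)
  if (min_p >= max_p) {
    stop("degenerate pore model: min level equals max level")
  }
  structure(
    list(k = as.integer(k), levels = levels,
         min_p = min_p, max_p = max_p,
         model_mean = mean(levels), model_std = pop_sd(levels)),
    class = "pore_model")
}

#' Load a pore model table
#'
#' Reads a tab-separated k-mer model with a header and at least the columns
#' `kmer` and `level_mean` (extra columns are ignored). A pore model maps
#' each k-mer to the expected current (pA) it produces in the nanopore; the
#' global minimum/maximum level and the mean/standard deviation over all
#' levels are derived from the table and drive binning and normalization.
#'
#' @param path path to the TSV file.
#' @param k k-mer length; the table must contain all `4^k` k-mers exactly once.
#' @return an object of class `pore_model` with fields `k`, `levels` (named
#'   numeric vector), `min_p`, `max_p`, `model_mean`, `model_std`.
#' @export
load_pore_model <- function(path, k) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("kmer", "level_mean") %in% names(tab))) {
    stop("pore model TSV must have columns 'kmer' and 'level_mean'")
  }
  kmers <- toupper(as.character(tab$kmer))
  lv <- tab$level_mean
  if (!is.numeric(lv)) {
    lv2 <- suppressWarnings(as.numeric(lv))
    if (any(is.na(lv2) & !is.na(lv))) stop("non-numeric level_mean values")
    lv <- lv2
  }
  if (anyDuplicated(kmers)) {
    stop("duplicate k-mers in pore model: ",
         paste(unique(kmers[duplicated(kmers)])[1:5], collapse = ", "))
  }
  expected <- all_kmers(k)
  missing <- setdiff(expected, kmers)
  if (length(missing) > 0L) {
    stop(length(missing), " of ", length(expected),
         " expected ", k, "-mers missing from pore model")
  }
  extra <- setdiff(kmers, expected)
  if (length(extra) > 0L) {
    stop("unexpected k-mers in pore model (wrong k?): ",
         paste(extra[1:5], collapse = ", "))
  }
  levels <- stats::setNames(lv, kmers)[expected]
  new_pore_model(k, levels)
}

#' Write a pore model table
#'
#' Inverse of [load_pore_model()]: writes a `kmer<TAB>level_mean` table that
#' round-trips the model exactly.
#'
#' @param model a `pore_model`.
#' @param path output path.
#' @export
write_pore_model <- function(model, path) {
  df <- data.frame(kmer = names(model$levels),
                   level_mean = unname(model$levels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic pore model
#'
#' Draws one expected level per k-mer uniformly from `level_range`. Stands in
#' for chemistry-specific model tables in simulations and tests; deterministic
#' for a fixed seed.
#'
#' @param k k-mer length, between 2 and 8 (guards the `4^k` alphabet size).
#' @param level_range numeric length-2, low and high expected current in pA.
#' @param seed integer seed.
#' @return a `pore_model`.
#' @export
generate_pore_model <- function(k, level_range = c(60, 120), seed = 1L) {
  if (k < 2L || k > 8L) stop("k must be in [2, 8]")
  if (length(level_range) != 2L || level_range[1] >= level_range[2]) {
    stop("level_range must be (low, high) with low < high")
  }
  kmers <- all_kmers(k)
  set.seed(seed)
  levels <- stats::setNames(
    stats::runif(length(kmers), level_range[1], level_range[2]), kmers)
  new_pore_model(k, levels)
}

#' Expected current trace of a nucleotide sequence
#'
#' Slides the pore model over `seq`: position `i` of the output is the
#' expected level of the k-mer starting at `i`, so the output has length
#' `nchar(seq) - k + 1`. The sequence must be pure ACGT; references with
#' ambiguity codes are split into contiguous segments first (see
#' [reference_segments()]).
#'
#' @param model a `pore_model`.
#' @param seq a nucleotide string over ACGT.
#' @return numeric vector of expected pA levels.
#' @export
expected_signal <- function(model, seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  k <- model$k
  if (n < k) stop("sequence shorter than k = ", k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% DNA_BASES)) {
    bad <- unique(chars[!chars %in% DNA_BASES])
    stop("disallowed characters in sequence: ",
         paste(bad, collapse = ", "),
         " (split references at ambiguity codes first)")
  }
  kmers <- substring(seq, seq_len(n - k + 1L), k:n)
  unname(model$levels[kmers])
}

#' Split a reference at ambiguity codes
#'
#' Returns the maximal contiguous ACGT stretches of `seq` that are at least
#' `min_len` long. Levels are never fabricated for N or other ambiguity
#' codes, which prevents spurious matches bridging assembly gaps.
#'
#' @param seq nucleotide string.
#' @param min_len minimum segment length to keep (typically the model's k).
#' @return character vector of segments (possibly empty).
#' @export
reference_segments <- function(seq, min_len = 1L) {
  seq <- toupper(seq)
  parts <- strsplit(seq, "[^ACGT]+")[[1L]]
  parts[nchar(parts) >= min_len]
}

#' Read a multi-FASTA of reference sequences
#'
#' @param path FASTA path.
#' @return named character vector, one element per record; names are the
#'   full description lines.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Reverse complement of a nucleotide string
#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf(
    "pore_model: k=%d, %d levels in [%.2f, %.2f] pA (mean %.2f, sd %.2f)\n",
    x$k, length(x$levels), x$min_p, x$max_p, x$model_mean, x$model_std))
  invisible(x)
}
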