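#' Simulation parameters
#'
#' Knobs of the synthetic squiggle generator. Defaults mirror the study
#' conditions used throughout the package: mean read length 10 000 bases,
#' amplitude-domain noise factor 2.0 (in units of a 1.0 pA base standard
#' deviation, so the factor reads directly as a pA standard deviation), and
#' dwell-time standard deviation 8.0 samples around a mean of 9 samples per
#' base (~4 kHz sampling at ~450 b/s). Stay/skip probabilities default to 0:
#' with noisy amplitudes and variable dwells, over- and under-segmentation
#' already arise naturally in event detection, and the explicit knobs exist
#' for targeted experiments.
#'
#' @param mean_read_length mean of the geometric read-length distribution
#'   (bases), truncated to the reference length.
#' @param amp_noise_sd_factor multiplier on the 1.0 pA base noise sd.
#' @param dwell_mean,dwell_sd samples per base: mean and sd of the
#'   truncated-normal dwell distribution (dwell >= 1).
#' @param p_stay probability of re-emitting the current k-mer as an extra
#'   event (over-segmentation).
#' @param p_skip probability of advancing two k-mers while emitting one
#'   event (under-segmentation).
#' @param seed integer seed; fixed seed gives bitwise-reproducible output.
#' @param read_length optional exact read length in bases, overriding the
#'   geometric draw (used e.g. to simulate full-reference reads).
#' @param base_sd base amplitude noise sd in pA (fixed at 1.0 so the factor
#'   is interpretable).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(mean_read_length = 10000, amp_noise_sd_factor = 2.0,
                       dwell_mean = 9, dwell_sd = 8.0,
                       p_stay = 0, p_skip = 0, seed = 1L,
                       read_length = NULL, base_sd = 1.0) {
  if (p_stay < 0 || p_stay >= 1 || p_skip < 0 || p_skip >= 1) {
    stop("stay/skip probabilities must be in [0, 1)")
  }
  if (dwell_mean < 1) stop("dwell_mean must be >= 1")
  structure(list(mean_read_length = mean_read_length,
                 amp_noise_sd_factor = amp_noise_sd_factor,
                 dwell_mean = dwell_mean, dwell_sd = dwell_sd,
                 p_stay = p_stay, p_skip = p_skip,
                 seed = as.integer(seed), read_length = read_length,
                 base_sd = base_sd),
            class = "sim_params")
}

# one dwell draw per emitted event: truncated normal, >= 1 sample
draw_dwells <- function(n, params) {
  d <- round(stats::rnorm(n, params$dwell_mean, params$dwell_sd))
  pmax(1L, as.integer(d))
}

#' Simulate one raw nanopore read
#'
#' Samples a substring of the reference (random start, random strand,
#' geometric length with the configured mean unless `read_length` pins it),
#' walks its k-mers, and emits `dwell` current samples per visited k-mer at
#' the pore-model level plus Gaussian amplitude noise. With probability
#' `p_stay` the current k-mer is re-emitted as an additional event (a stay);
#' with probability `p_skip` the walk advances two k-mers while emitting one
#' (a skip). Truth labels (source, class, strand, start, length, and the
#' originating k-mer index per sample) are returned for evaluation.
#'
#' @param ref nucleotide string (ACGT).
#' @param model a `pore_model`.
#' @param params a [sim_params()]; `params$seed` drives all randomness.
#' @param read_id identifier.
#' @param class_name truth class label to record.
#' @param source_name truth source label to record.
#' @return a list of class `simulated_read` with `read_id`, `samples`, and
#'   `truth` (list with `source`, `class`, `strand`, `start`, `length`,
#'   `seq`, `kmer_index`).
#' @export
simulate_read <- function(ref, model, params = sim_params(),
                          read_id = "read1", class_name = NA_character_,
                          source_name = "ref") {
  k <- model$k
  L <- nchar(ref)
  if (L < k + 1L) stop("reference shorter than k + 1")
  set.seed(params$seed)
  len <- if (!is.null(params$read_length)) {
    min(as.integer(params$read_length), L)
  } else {
    min(L, max(k + 1L, stats::rgeom(1L, 1 / params$mean_read_length) + 1L))
  }
  start <- sample.int(L - len + 1L, 1L)
  strand <- sample(c("+", "-"), 1L)
  sub <- substr(ref, start, start + len - 1L)
  walk_seq <- if (strand == "-") revcomp(sub) else sub
  levels <- expected_signal(model, walk_seq)
  n_kmers <- length(levels)

  # k-mer walk with stays and skips
  if (params$p_stay == 0 && params$p_skip == 0) {
    emit <- seq_len(n_kmers)
  } else {
    emit <- integer(0)
    p <- 1L
    while (p <= n_kmers) {
      emit <- c(emit, p)
      while (stats::runif(1L) < params$p_stay) emit <- c(emit, p)
      p <- p + if (stats::runif(1L) < params$p_skip) 2L else 1L
    }
  }
  dwells <- draw_dwells(length(emit), params)
  total <- sum(dwells)
  noise_sd <- params$amp_noise_sd_factor * params$base_sd
  samples <- rep(levels[emit], dwells)
  if (noise_sd > 0) samples <- samples + stats::rnorm(total, 0, noise_sd)
  structure(list(
    read_id = read_id, samples = samples,
    truth = list(source = source_name, class = class_name, strand = strand,
                 start = start, length = len, seq = sub,
                 kmer_index = rep(emit, dwells))),
    class = "simulated_read")
}

#' Simulate a labeled dataset of reads
#'
#' Draws reads from the references proportionally to a class mixture and
#' returns them together with a truth table.
#'
#' @param refs data.frame with columns `name`, `class`, `seq` (and
#'   optionally `polarity`).
#' @param n_reads number of reads (>= 1).
#' @param model a `pore_model`.
#' @param params a [sim_params()]; per-read seeds are derived from
#'   `params$seed`.
#' @param mixture named numeric vector of class weights (default uniform
#'   over classes); renormalized with a warning if it does not sum to 1.
#' @return list with `reads` (named list of sample vectors), `truth`
#'   (data.frame: `read_id`, `source`, `class`, `strand`, `start`,
#'   `length`), and `sim_reads` (the full `simulated_read` objects).
#' @export
simulate_dataset <- function(refs, n_reads, model, params = sim_params(),
                             mixture = NULL) {
  if (nrow(refs) == 0L) stop("empty reference list")
  if (n_reads < 1L) stop("n_reads must be >= 1")
  classes <- unique(refs$class)
  if (is.null(mixture)) {
    mixture <- stats::setNames(rep(1 / length(classes), length(classes)),
                               classes)
  }
  if (!all(classes %in% names(mixture))) stop("mixture missing classes")
  if (abs(sum(mixture) - 1) > 1e-9) {
    warning("mixture weights renormalized to sum to 1")
    mixture <- mixture / sum(mixture)
  }
  set.seed(params$seed)
  read_cls <- sample(names(mixture), n_reads, replace = TRUE, prob = mixture)
  seeds <- sample.int(.Machine$integer.max, n_reads)
  sim_reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    cand <- which(refs$class == read_cls[i])
    ri <- if (length(cand) == 1L) cand else cand[1L + (seeds[i] %% length(cand))]
    p <- params
    p$seed <- seeds[i]
    sim_reads[[i]] <- simulate_read(
      refs$seq[ri], model, p, read_id = sprintf("read%04d", i),
      class_name = refs$class[ri], source_name = refs$name[ri])
  }
  truth <- do.call(rbind, lapply(sim_reads, function(sr) {
    data.frame(read_id = sr$read_id, source = sr$truth$source,
               class = sr$truth$class, strand = sr$truth$strand,
               start = sr$truth$start, length = sr$truth$length,
               stringsAsFactors = FALSE)
  }))
  reads <- stats::setNames(lapply(sim_reads, `[[`, "samples"),
                           vapply(sim_reads, `[[`, character(1L), "read_id"))
  list(reads = reads, truth = truth, sim_reads = sim_reads)
}

#' Write / read a truth table TSV
#' @param truth truth data.frame from [simulate_dataset()].
#' @param path file path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Evaluate classifications against truth
#'
#' Joins a classification report with a truth table by `read_id` and
#' computes confusion-matrix metrics. Multi-class: accuracy and
#' length-weighted accuracy (each read weighted by its base length,
#' prioritizing long reads). Binary (when `positive_classes` is given or
#' the report's index had positive classes): precision, recall, and F1 in
#' both unweighted and length-weighted forms.
#'
#' @param report classification report data.frame (from
#'   [classify_reads()] / [cmd_classify()]).
#' @param truth truth data.frame with `read_id`, `class`, `length`.
#' @param positive_classes character vector of class names treated as the
#'   positive class for binary metrics (NULL for multi-class only).
#' @return named list of metrics; also contains `n_reads` and the
#'   confusion table.
#' @export
evaluate_classification <- function(report, truth, positive_classes = NULL) {
  if (nrow(truth) == 0L) stop("empty truth table")
  miss <- setdiff(report$read_id, truth$read_id)
  if (length(miss) > 0L) {
    stop("read_ids missing from truth: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  m <- merge(report, truth, by = "read_id", suffixes = c("", ".truth"))
  if (nrow(m) == 0L) stop("no overlapping read_ids")
  w <- as.numeric(m$length)
  correct <- m$predicted_class == m$class
  out <- list(
    n_reads = nrow(m),
    accuracy = mean(correct),
    accuracy_weighted = sum(w * correct) / sum(w),
    confusion = table(truth = m$class, predicted = m$predicted_class))
  if (!is.null(positive_classes)) {
    tp_sel <- m$class %in% positive_classes &
      m$predicted_class %in% positive_classes
    fp_sel <- !(m$class %in% positive_classes) &
      m$predicted_class %in% positive_classes
    fn_sel <- m$class %in% positive_classes &
      !(m$predicted_class %in% positive_classes)
    prf <- function(tp, fp, fn) {
      precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
        2 * precision * recall / (precision + recall) else NA_real_
      list(precision = precision, recall = recall, f1 = f1)
    }
    u <- prf(sum(tp_sel), sum(fp_sel), sum(fn_sel))
    lw <- prf(sum(w[tp_sel]), sum(w[fp_sel]), sum(w[fn_sel]))
    out$precision <- u$precision
    out$recall <- u$recall
    out$f1 <- u$f1
    out$precision_weighted <- lw$precision
    out$recall_weighted <- lw$recall
    out$f1_weighted <- lw$f1
  }
  out
}
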