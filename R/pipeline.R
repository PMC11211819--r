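#' Project references into a shredded, indexed collection
#'
#' Convenience wrapper used by [cmd_build()] and the simulators' test
#' harnesses: splits each reference at ambiguity codes, projects every
#' contiguous segment through the pore model into the bin alphabet (both
#' strands by default), shreds, and returns the `doc_collection`.
#'
#' @param refs data.frame with columns `name`, `class`, `seq`, and
#'   optionally `polarity`.
#' @param model a `pore_model`.
#' @param cfg a [binning_config()].
#' @param shred_size symbols per shred.
#' @param both_strands index the reverse-complement projection too
#'   (default; nanopore reads arrive from either strand).
#' @return a `doc_collection`.
#' @export
build_reference_collection <- function(refs, model, cfg,
                                       shred_size = 100000L,
                                       both_strands = TRUE) {
  docs <- list()
  seg_seqs <- character()
  for (i in seq_len(nrow(refs))) {
    segs <- reference_segments(refs$seq[i], min_len = model$k)
    if (length(segs) == 0L) {
      warning("reference ", refs$name[i], " has no usable segment; skipped")
      next
    }
    for (s in segs) {
      docs[[length(docs) + 1L]] <- list(
        name = refs$name[i], class = refs$class[i],
        polarity = if ("polarity" %in% names(refs)) refs$polarity[i]
                   else "plain",
        bins = reference_to_binseq(s, model, cfg))
      seg_seqs <- c(seg_seqs, s)
    }
  }
  if (length(docs) == 0L) stop("no usable reference segments")
  coll <- shred_collection(docs, shred_size)
  if (both_strands) {
    for (di in seq_along(docs)) {
      rc <- reference_to_binseq(revcomp(seg_seqs[di]), model, cfg)
      coll <- add_reverse_segments(coll, di, rc)
    }
  }
  coll
}

classify_one <- function(index, samples, mode, cfg, ev_params, read_id) {
  events <- detect_events(samples, ev_params)
  norm <- normalize_events(events, index$model_stats)
  bins <- hpc_compress(bin_events(norm$events, index$binning))
  prof <- compute_pmls(index, bins, read_id = read_id)$profile
  scores <- score_documents(prof, index, cfg)
  if (mode == "binary") {
    classify_binary(scores, index, cfg, read_id = read_id)
  } else {
    classify_multiclass(scores, index, read_id = read_id)
  }
}

empty_report <- function() {
  data.frame(read_id = character(), predicted_class = character(),
             top_shred = integer(), top_score = numeric(),
             null_score = numeric(), spike_ratio = numeric(),
             n_peaks = integer(), flags = character(),
             chunk_count = integer(), stringsAsFactors = FALSE)
}

#' Classify a set of reads
#'
#' Runs the full query pipeline per read: event detection, per-read
#' normalization onto the model scale, binning, homopolymer compression,
#' streaming PML computation, and the complexity-weighted peak vote. In
#' chunk mode the signal is consumed in fixed-size chunks (default 4000
#' samples, roughly one second of sequencing) and a decision row is emitted
#' per (read, chunk count) by reprocessing the growing signal prefix, so
#' normalization always reflects everything seen so far; the final chunk row
#' is identical to the whole-read decision.
#'
#' @param index a `ref_index` carrying `binning` and `model_stats` metadata.
#' @param reads named list of numeric sample vectors.
#' @param mode `"multi"` or `"binary"`.
#' @param cfg a [classification_config()].
#' @param event_params [event_detection_params()]; defaults to the ones
#'   stored in the index, else the package defaults.
#' @param chunks `"all"` for one whole-read decision per read, or an integer
#'   N for decision rows at chunk counts 1..N (capped per read).
#' @param chunk_size samples per chunk.
#' @return a report data.frame with columns `read_id`, `predicted_class`,
#'   `top_shred`, `top_score`, `null_score`, `spike_ratio`, `n_peaks`,
#'   `flags`, `chunk_count` (NA in whole-read mode).
#' @export
classify_reads <- function(index, reads, mode = c("multi", "binary"),
                           cfg = classification_config(),
                           event_params = NULL, chunks = "all",
                           chunk_size = 4000L) {
  mode <- match.arg(mode)
  if (is.null(index$binning) || is.null(index$model_stats)) {
    stop("index lacks binning/model metadata; rebuild with cmd_build")
  }
  ev <- event_params %||% index$event_params %||% event_detection_params()
  if (length(reads) == 0L) return(empty_report())
  rows <- list()
  for (id in names(reads)) {
    samples <- reads[[id]]
    if (identical(chunks, "all")) {
      row <- classify_one(index, samples, mode, cfg, ev, id)
      row$chunk_count <- NA_integer_
      rows[[length(rows) + 1L]] <- row
    } else {
      n_chunks <- ceiling(length(samples) / chunk_size)
      for (cc in seq_len(min(as.integer(chunks), n_chunks))) {
        prefix <- samples[seq_len(min(length(samples), cc * chunk_size))]
        row <- classify_one(index, prefix, mode, cfg, ev, id)
        row$chunk_count <- cc
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Write / read a classification report TSV
#' @param report report data.frame.
#' @param path file path.
#' @export
write_report_tsv <- function(report, path) {
  cols <- c("read_id", "predicted_class", "top_shred", "top_score",
            "null_score", "spike_ratio", "n_peaks", "flags", "chunk_count")
  if (nrow(report) == 0L) report <- empty_report()
  utils::write.table(report[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

read_class_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("record", "class")
  if (!all(need %in% names(tab))) {
    stop("class manifest needs columns: record, class (optional polarity)")
  }
  if (!"polarity" %in% names(tab)) tab$polarity <- "plain"
  tab
}

match_records <- function(record_names, manifest) {
  first_tok <- sub("\\s.*$", "", record_names)
  idx <- match(record_names, manifest$record)
  idx[is.na(idx)] <- match(first_tok[is.na(idx)], manifest$record)
  if (any(is.na(idx))) {
    stop("reference record(s) not in class manifest: ",
         paste(record_names[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Build a reference index from files
#'
#' Reads a multi-FASTA of references, a class manifest TSV
#' (`record<TAB>class<TAB>polarity`), and a pore model TSV; projects and
#' shreds the references; builds the run-length BWT index; and writes the
#' index directory plus a FASTA of the ASCII-encoded forward bin sequences
#' (`<source_name>|<segment_index>` headers). The build is atomic: output
#' appears under `out_dir` only on success.
#'
#' @param ref_fasta reference FASTA path.
#' @param classes_tsv class manifest path.
#' @param pore_model_tsv pore model path.
#' @param out_dir output index directory.
#' @param k pore-model k-mer length.
#' @param n_bins alphabet size.
#' @param shred_size symbols per shred.
#' @param both_strands index both strands (default TRUE).
#' @param complexity_method see [build_index()].
#' @param event_params [event_detection_params()] to record in the index.
#' @param quiet suppress the build summary.
#' @return the loaded `ref_index`, invisibly.
#' @export
cmd_build <- function(ref_fasta, classes_tsv, pore_model_tsv, out_dir,
                      k = 6L, n_bins = 6L, shred_size = 100000L,
                      both_strands = TRUE,
                      complexity_method = "delta",
                      event_params = event_detection_params(),
                      quiet = FALSE) {
  for (p in c(ref_fasta, classes_tsv, pore_model_tsv)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  model <- load_pore_model(pore_model_tsv, k)
  manifest <- read_class_manifest(classes_tsv)
  seqs <- read_reference_fasta(ref_fasta)
  idx <- match_records(names(seqs), manifest)
  refs <- data.frame(name = names(seqs), class = manifest$class[idx],
                     polarity = manifest$polarity[idx],
                     seq = unname(seqs), stringsAsFactors = FALSE)
  cfg <- binning_config(model, n_bins = n_bins)
  coll <- build_reference_collection(refs, model, cfg, shred_size,
                                     both_strands)
  index <- build_index(coll, complexity_method = complexity_method,
                       binning = cfg,
                       model_stats = list(model_mean = model$model_mean,
                                          model_std = model$model_std),
                       event_params = event_params)
  tmp <- paste0(out_dir, ".build-tmp")
  unlink(tmp, recursive = TRUE)
  serialize_index(index, tmp)
  # forward binned reference FASTA, one record per contiguous segment
  fwd <- coll$segments[vapply(coll$segments, function(s) s$strand == "+",
                              logical(1L))]
  src <- vapply(fwd, function(s) s$source, character(1L))
  seg_idx <- stats::ave(seq_along(fwd), src, FUN = seq_along)
  strs <- vapply(fwd, function(s) {
    encode_ascii(bin_seq(s$symbols, coll$n_bins))
  }, character(1L))
  bs <- Biostrings::BStringSet(strs)
  names(bs) <- paste0(src, "|", seg_idx)
  Biostrings::writeXStringSet(bs, file.path(tmp, "binned_refs.fa"))
  unlink(out_dir, recursive = TRUE)
  if (!file.rename(tmp, out_dir)) {
    stop("failed to move index into place at ", out_dir)
  }
  if (!quiet) {
    message(sprintf(
      "built index: n=%d r=%d n/r=%.2f shreds=%d classes=%d bins=%d",
      index$n, index$r, index$n / index$r, nrow(index$shreds),
      nrow(index$class_table), index$n_bins))
  }
  invisible(index)
}

#' Classify a signal file against an index directory
#'
#' @param index_dir index directory from [cmd_build()].
#' @param signal_tsv signal TSV (`read_id<TAB>comma-separated floats`).
#' @param out_tsv output report path.
#' @param mode `"multi"` or `"binary"`.
#' @param chunks `"all"` or integer chunk budget (see [classify_reads()]).
#' @param spike_ratio binary spike-ratio threshold.
#' @param complexity_correction apply the complexity weights.
#' @param chunk_size samples per chunk.
#' @param n_bins if given, must match the index (config compatibility
#'   check).
#' @return the report data.frame, invisibly.
#' @export
cmd_classify <- function(index_dir, signal_tsv, out_tsv,
                         mode = c("multi", "binary"), chunks = "all",
                         spike_ratio = 1.0, complexity_correction = TRUE,
                         chunk_size = 4000L, n_bins = NULL) {
  mode <- match.arg(mode)
  index <- load_index(index_dir)
  if (!is.null(n_bins) && as.integer(n_bins) != index$n_bins) {
    stop("configured n_bins (", n_bins, ") does not match index (",
         index$n_bins, ")")
  }
  reads <- read_signal_tsv(signal_tsv)
  cfg <- classification_config(spike_ratio_threshold = spike_ratio,
                               complexity_correction = complexity_correction)
  report <- classify_reads(index, reads, mode = mode, cfg = cfg,
                           chunks = chunks, chunk_size = chunk_size)
  write_report_tsv(report, out_tsv)
  invisible(report)
}

#' Simulate a dataset from reference files
#'
#' @param ref_fasta,classes_tsv,pore_model_tsv input files as in
#'   [cmd_build()].
#' @param n number of reads.
#' @param seed mandatory integer seed.
#' @param out_signal,out_truth output paths for the signal and truth TSVs.
#' @param k pore-model k-mer length.
#' @param params a [sim_params()] (its seed is overridden by `seed`).
#' @param mixture optional named class mixture.
#' @return the `simulate_dataset()` result, invisibly.
#' @export
cmd_simulate <- function(ref_fasta, classes_tsv, pore_model_tsv, n, seed,
                         out_signal, out_truth, k = 6L,
                         params = sim_params(), mixture = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  model <- load_pore_model(pore_model_tsv, k)
  manifest <- read_class_manifest(classes_tsv)
  seqs <- read_reference_fasta(ref_fasta)
  idx <- match_records(names(seqs), manifest)
  refs <- data.frame(name = names(seqs), class = manifest$class[idx],
                     seq = unname(seqs), stringsAsFactors = FALSE)
  params$seed <- as.integer(seed)
  ds <- simulate_dataset(refs, n, model, params, mixture)
  write_signal_tsv(ds$reads, out_signal)
  write_truth_tsv(ds$truth, out_truth)
  invisible(ds)
}

#' Evaluate a report file against a truth file
#'
#' @param report_tsv,truth_tsv input paths.
#' @param positive_classes class names treated as positive for binary
#'   metrics (NULL: multi-class metrics only).
#' @param out optional path for a metrics TSV.
#' @return metrics list from [evaluate_classification()], invisibly.
#' @export
cmd_evaluate <- function(report_tsv, truth_tsv, positive_classes = NULL,
                         out = NULL) {
  report <- read_report_tsv(report_tsv)
  truth <- read_truth_tsv(truth_tsv)
  metrics <- evaluate_classification(report, truth, positive_classes)
  if (!is.null(out)) {
    keep <- metrics[setdiff(names(metrics), "confusion")]
    df <- data.frame(metric = names(keep),
                     value = unlist(keep, use.names = FALSE))
    utils::write.table(df, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(metrics)
}
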