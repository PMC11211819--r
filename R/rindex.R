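# Encoded alphabet used by the index text:
#   0 = unique end-of-text sentinel (last position only)
#   1 = shred separator (shared by all shreds, never matchable)
#   bin b -> b + 2
SYM_OFFSET <- 2L

#' Shred a document collection
#'
#' Partitions each document's bin sequence into consecutive, non-overlapping
#' shreds of `shred_size` symbols (the final partial shred of a document is
#' kept as its own shred). Each shred receives a distinct dense document
#' label, which is what the sampled document array reports during matching,
#' so a match localizes to a specific reference region rather than a whole
#' genome.
#'
#' @param docs list of documents, each a list with `name` (source name),
#'   `class` (class name), `bins` (a `bin_seq`), and optionally `polarity`
#'   (`"positive"`, `"null"`, or `"plain"`, default `"plain"`).
#' @param shred_size symbols per shred (>= 2); default 100000.
#' @return an object of class `doc_collection` with `segments` (one text
#'   segment per shred, each carrying its shred id), `shreds` (per-shred
#'   table), `class_table`, `doc_shreds` (per input document: shred ids and
#'   forward cut points, used for strand mirroring), `shred_size`, `n_bins`.
#' @export
shred_collection <- function(docs, shred_size = 100000L) {
  shred_size <- as.integer(shred_size)
  if (shred_size < 2L) stop("shred_size must be >= 2")
  if (length(docs) == 0L) stop("empty document collection")
  keep <- vapply(docs, function(d) length(d$bins$symbols) > 0L, logical(1L))
  if (any(!keep)) {
    warning(sum(!keep), " empty document(s) skipped")
    docs <- docs[keep]
  }
  if (length(docs) == 0L) stop("all documents empty")
  n_bins <- docs[[1L]]$bins$n_bins
  ok <- vapply(docs, function(d) d$bins$n_bins == n_bins, logical(1L))
  if (!all(ok)) stop("documents disagree on n_bins")

  class_names <- vapply(docs, function(d) as.character(d$class), character(1L))
  polarity <- vapply(docs, function(d) {
    p <- if (is.null(d$polarity)) "plain" else as.character(d$polarity)
    match.arg(p, c("plain", "positive", "null"))
  }, character(1L))
  uc <- unique(class_names)
  class_table <- data.frame(
    class_id = seq_along(uc) - 1L,
    class_name = uc,
    polarity = polarity[match(uc, class_names)],
    stringsAsFactors = FALSE)

  segments <- list()
  shred_rows <- list()
  doc_shreds <- vector("list", length(docs))
  next_id <- 0L
  for (di in seq_along(docs)) {
    d <- docs[[di]]
    L <- length(d$bins$symbols)
    cuts <- unique(c(seq(0L, L, by = shred_size), L))
    m <- length(cuts) - 1L
    ids <- next_id + seq_len(m) - 1L
    cid <- class_table$class_id[match(class_names[di], class_table$class_name)]
    for (j in seq_len(m)) {
      sym <- d$bins$symbols[(cuts[j] + 1L):cuts[j + 1L]]
      segments[[length(segments) + 1L]] <-
        list(shred_id = ids[j], class_id = cid, source = d$name,
             strand = "+", symbols = as.integer(sym))
      shred_rows[[length(shred_rows) + 1L]] <- data.frame(
        shred_id = ids[j], class_id = cid, source = d$name,
        offset = cuts[j], length = cuts[j + 1L] - cuts[j],
        stringsAsFactors = FALSE)
    }
    doc_shreds[[di]] <- list(ids = ids, cuts = cuts, length = L)
    next_id <- next_id + m
  }
  structure(list(segments = segments,
                 shreds = do.call(rbind, shred_rows),
                 class_table = class_table,
                 doc_shreds = doc_shreds,
                 shred_size = shred_size,
                 n_bins = n_bins),
            class = "doc_collection")
}

#' Add reverse-strand text for a document
#'
#' Nanopore reads arrive from either strand, so the reference index carries
#' both the forward-projected bin sequence and the reverse-complement
#' projection of every document. The reverse sequence is cut at
#' proportionally mirrored positions of the forward shred boundaries and
#' each piece is assigned the mirrored forward shred id, so both strands of
#' one reference region vote for the same shred.
#'
#' @param coll a `doc_collection`.
#' @param doc_index index of the document (in the `docs` list passed to
#'   [shred_collection()]) whose reverse projection is being added.
#' @param rc_bins `bin_seq` of the reverse-complement projection.
#' @return the updated `doc_collection`.
#' @export
add_reverse_segments <- function(coll, doc_index, rc_bins) {
  if (doc_index < 1L || doc_index > length(coll$doc_shreds)) {
    stop("unknown document index ", doc_index)
  }
  info <- coll$doc_shreds[[doc_index]]
  Lf <- info$length
  Lr <- length(rc_bins$symbols)
  if (Lr == 0L) return(coll)
  m <- length(info$cuts) - 1L
  # mirrored cut points: piece j (0-based) corresponds to forward shred m-1-j
  crev <- round(Lr * (Lf - rev(info$cuts)) / Lf)
  cls <- coll$shreds$class_id[match(info$ids[1L], coll$shreds$shred_id)]
  src <- coll$shreds$source[match(info$ids[1L], coll$shreds$shred_id)]
  for (j in seq_len(m)) {
    from <- crev[j] + 1L
    to <- crev[j + 1L]
    if (to < from) next
    coll$segments[[length(coll$segments) + 1L]] <-
      list(shred_id = info$ids[m - j + 1L], class_id = cls, source = src,
           strand = "-",
           symbols = as.integer(rc_bins$symbols[from:to]))
  }
  coll
}

# Build the encoded text + per-position shred labels for a collection.
collection_text <- function(coll) {
  segs <- coll$segments
  parts <- vector("list", length(segs))
  docs <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    parts[[i]] <- c(segs[[i]]$symbols + SYM_OFFSET, 1L)
    docs[[i]] <- rep(segs[[i]]$shred_id, length(segs[[i]]$symbols) + 1L)
  }
  text <- unlist(parts, use.names = FALSE)
  text[length(text)] <- 0L  # final separator is the unique sentinel
  list(text = text, doc_of_pos = unlist(docs, use.names = FALSE))
}

# per-symbol run lists + cumulative counts + C table for LF mapping
prepare_rank <- function(run_sym, run_len, n_sym) {
  totals <- integer(n_sym)
  agg <- tapply(run_len, run_sym, sum)
  totals[as.integer(names(agg)) + 1L] <- as.integer(agg)
  C <- c(0L, cumsum(totals))[seq_len(n_sym)]
  ord <- order(run_sym, seq_along(run_sym))
  sym_runs <- (seq_along(run_sym) - 1L)[ord]
  counts <- tabulate(run_sym + 1L, nbins = n_sym)
  sym_off <- c(0L, cumsum(counts))
  # cumulative count of each symbol before each of its runs
  lens <- run_len[ord]
  sym_cum <- integer(length(lens))
  for (c in seq_len(n_sym)) {
    lo <- sym_off[c] + 1L
    hi <- sym_off[c + 1L]
    if (hi >= lo) {
      sym_cum[lo:hi] <- c(0L, cumsum(lens[lo:hi]))[seq_len(hi - lo + 1L)]
    }
  }
  list(C = as.integer(C), sym_runs = as.integer(sym_runs),
       sym_off = as.integer(sym_off), sym_cum = as.integer(sym_cum))
}

#' Build the run-length BWT reference index
#'
#' Concatenates the collection's text segments (separator-delimited), builds
#' the suffix array and BWT, run-length encodes, derives the MONI-style
#' threshold structure (per pair of consecutive same-symbol runs, the row of
#' minimum LCP between them), samples shred labels at the first and last row
#' of every run, and computes per-shred sequence complexity. The suffix and
#' LCP arrays are discarded after construction; pseudo-matching-length
#' queries need neither.
#'
#' @param coll a `doc_collection`.
#' @param complexity_method `"delta"` (substring complexity) or `"entropy"`
#'   (order-0 empirical entropy); see [shred_complexity()].
#' @param binning,model_stats,event_params optional metadata stored with the
#'   index so classification needs no separate pore-model file: a
#'   [binning_config()], a list with `model_mean`/`model_std`, and the
#'   [event_detection_params()] used.
#' @return an object of class `ref_index`.
#' @export
build_index <- function(coll, complexity_method = c("delta", "entropy"),
                        binning = NULL, model_stats = NULL,
                        event_params = NULL) {
  complexity_method <- match.arg(complexity_method)
  if (!inherits(coll, "doc_collection")) stop("coll must be a doc_collection")
  if (length(coll$segments) == 0L) stop("empty collection")
  tx <- collection_text(coll)
  core <- build_index_cpp(tx$text, tx$doc_of_pos)
  n_sym <- coll$n_bins + SYM_OFFSET
  run_len <- diff(c(core$run_start, core$n))
  rk <- prepare_rank(core$run_sym, run_len, n_sym)

  # per-shred complexity, normalized to (0, 1] across the collection;
  # computed on the forward text segment of each shred
  shreds <- coll$shreds
  fwd <- coll$segments[vapply(coll$segments, function(s) s$strand == "+",
                              logical(1L))]
  fwd_ids <- vapply(fwd, function(s) s$shred_id, integer(1L))
  raw <- vapply(shreds$shred_id, function(id) {
    seg <- fwd[[match(id, fwd_ids)]]
    shred_complexity(bin_seq(seg$symbols, coll$n_bins),
                     method = complexity_method)
  }, numeric(1L))
  shreds$complexity_raw <- raw
  shreds$C_d <- raw / max(raw)

  structure(list(
    n = core$n, r = core$r, n_bins = coll$n_bins,
    run_start = core$run_start, run_sym = core$run_sym, run_len = run_len,
    doc_first = core$doc_first, doc_last = core$doc_last, thr = core$thr,
    C = rk$C, sym_runs = rk$sym_runs, sym_off = rk$sym_off,
    sym_cum = rk$sym_cum,
    start_doc = core$start_doc,
    shreds = shreds, class_table = coll$class_table,
    shred_size = coll$shred_size,
    complexity_method = complexity_method,
    binning = binning, model_stats = model_stats,
    event_params = event_params),
    class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf(
    "ref_index: n=%d, r=%d (n/r=%.2f), %d bins, %d shreds, %d classes\n",
    x$n, x$r, x$n / x$r, x$n_bins, nrow(x$shreds), nrow(x$class_table)))
  invisible(x)
}

new_pml_profile <- function(P, D, read_id, query) {
  structure(list(P = as.integer(P), D = as.integer(D),
                 read_id = read_id, query = query),
            class = "pml_profile")
}

#' Compute pseudo-matching lengths against the index
#'
#' Single right-to-left streaming pass over the query maintaining the
#' backward-search row interval of the current match, one sampled row
#' inside it, the match length, and the current shred label. While the
#' interval stays non-empty the match extends by one per symbol (hopping to
#' a labeled run boundary inside the interval when the tracked row's symbol
#' differs, with ties broken by the threshold structure); when no extension
#' exists anywhere, the matcher jumps to the nearest run of the wanted
#' symbol in the threshold direction and the length resets. `P[i]` is thus
#' the length of the longest uninterrupted backward match ending at query
#' position `i` -- a matching statistic truncated at mismatch resets -- and
#' `D[i]` the shred label of a row holding that match. The returned state
#' lets successive chunks of one read resume exactly where the previous
#' chunk stopped.
#'
#' @param index a `ref_index`.
#' @param query a `bin_seq` over the same alphabet as the index.
#' @param state state returned by a previous call for the same read, or
#'   `NULL` for a cold start (row parked at the last text row).
#' @param read_id identifier stored in the profile.
#' @return list with `profile` (a `pml_profile` with fields `P`, `D`,
#'   `read_id`, `query`) and `state`.
#' @export
compute_pmls <- function(index, query, state = NULL, read_id = "read") {
  if (query$n_bins != index$n_bins) {
    stop("query alphabet (", query$n_bins, ") does not match index (",
         index$n_bins, ")")
  }
  if (is.null(state)) {
    state <- list(row = index$n - 1L, len = 0L, doc = index$start_doc,
                  lo = 0L, hi = index$n - 1L)
  }
  q <- query$symbols + SYM_OFFSET
  res <- compute_pmls_cpp(q, index$run_start, index$run_sym,
                          index$doc_first, index$doc_last, index$thr,
                          index$C, index$sym_runs, index$sym_off,
                          index$sym_cum, index$n,
                          state$row, state$len, state$doc,
                          state$lo, state$hi)
  list(profile = new_pml_profile(res$P, res$D, read_id, query$symbols),
       state = list(row = res$row, len = res$len, doc = res$doc,
                    lo = res$lo, hi = res$hi))
}

#' Exact matching statistics by brute force (test oracle)
#'
#' `MS[i]` is the length of the longest prefix of `query[i:]` occurring
#' verbatim in any text segment of the collection, found by naive substring
#' search. Intended as an independent oracle at small scale: pseudo-matching
#' lengths are truncated matching statistics, so `0 <= P[i] <= MS[i]`
#' everywhere.
#'
#' @param query a `bin_seq`.
#' @param coll a `doc_collection`.
#' @return integer vector of matching statistics.
#' @export
matching_statistics_oracle <- function(query, coll) {
  q <- encode_ascii(query)
  m <- nchar(q)
  texts <- vapply(coll$segments, function(s) {
    encode_ascii(bin_seq(s$symbols, coll$n_bins))
  }, character(1L))
  occurs <- function(sub) any(grepl(sub, texts, fixed = TRUE))
  MS <- integer(m)
  prev <- 0L
  for (i in seq_len(m)) {
    l <- max(prev - 1L, 0L)
    if (l > 0L && !occurs(substr(q, i, i + l - 1L))) {
      # cannot happen for true matching statistics; recompute from scratch
      l <- 0L
    }
    while (i + l <= m && occurs(substr(q, i, i + l))) l <- l + 1L
    MS[i] <- l
    prev <- l
  }
  MS
}

#' Check that every labeled match occurs in its labeled shred
#'
#' Soundness check for the sampled document array: for every position with
#' `P[i] > 0`, the matched substring `query[i:(i + P[i] - 1)]` must occur in
#' the text of shred `D[i]` (either strand).
#'
#' @param profile a `pml_profile` (as returned by [compute_pmls()]).
#' @param coll the `doc_collection` the index was built from.
#' @return `TRUE`, or `FALSE` with attribute `first_violation` (position).
#' @export
label_validity_check <- function(profile, coll) {
  q <- encode_ascii(bin_seq(profile$query, coll$n_bins))
  seg_ids <- vapply(coll$segments, function(s) s$shred_id, integer(1L))
  seg_txt <- vapply(coll$segments, function(s) {
    encode_ascii(bin_seq(s$symbols, coll$n_bins))
  }, character(1L))
  for (i in seq_along(profile$P)) {
    p <- profile$P[i]
    if (p <= 0L) next
    sub <- substr(q, i, i + p - 1L)
    txts <- seg_txt[seg_ids == profile$D[i]]
    if (!any(grepl(sub, txts, fixed = TRUE))) {
      out <- FALSE
      attr(out, "first_violation") <- i
      return(out)
    }
  }
  TRUE
}
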