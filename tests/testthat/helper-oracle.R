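# Independent brute-force oracles. These deliberately share nothing with the
# package implementation beyond the documented encoding conventions, so an
# agreement between the two is evidence of correctness, not of shared bugs.

# Direct, branch-by-branch transcription of the binning rule:
# values below the range clamp to bin 0, above it to the top bin, the top
# boundary value falls in the (closed) top bin, and everything else goes to
# floor((e - min) / s).
oracle_bin_value <- function(e_c, cfg) {
  out <- integer(length(e_c))
  for (i in seq_along(e_c)) {
    e <- e_c[i]
    if (e < cfg$min_p) {
      out[i] <- 0L
    } else if (e > cfg$max_p) {
      out[i] <- cfg$n_bins - 1L
    } else {
      b <- floor((e - cfg$min_p) / cfg$s_p)
      if (b >= cfg$n_bins) b <- cfg$n_bins - 1L
      out[i] <- as.integer(b)
    }
  }
  out
}

# Brute-force suffix array via radix string sort. `text` is the encoded
# integer text ending in the unique smallest sentinel 0; symbols are mapped
# to consecutive ASCII characters so byte order equals symbol order.
oracle_suffix_array <- function(text) {
  n <- length(text)
  suf <- vapply(seq_len(n), function(i) {
    intToUtf8(text[i:n] + 33L)
  }, character(1L))
  order(suf, method = "radix") - 1L  # 0-based to match the C++ side
}

oracle_lcp <- function(text, sa) {
  n <- length(text)
  lcp <- integer(n)
  for (i in seq_len(n - 1L)) {
    a <- sa[i] + 1L
    b <- sa[i + 1L] + 1L
    h <- 0L
    while (a + h <= n && b + h <= n && text[a + h] == text[b + h]) {
      h <- h + 1L
    }
    lcp[i + 1L] <- h
  }
  lcp
}

# Full brute-force index: BWT, runs, document samples, thresholds. Mirrors
# the documented conventions: BWT[i] = text[(sa[i] - 1) mod n]; the
# threshold of run j (symbol c, previous same-symbol run p ending at row
# e_p) is the row in (e_p, run_start[j]] with minimum LCP, smallest row on
# ties; the first run of each symbol has threshold 0.
oracle_index <- function(text, doc_of_pos) {
  n <- length(text)
  sa <- oracle_suffix_array(text)
  lcp <- oracle_lcp(text, sa)
  bwt <- text[((sa - 1L) %% n) + 1L]
  doc_at_row <- doc_of_pos[sa + 1L]

  is_start <- c(TRUE, bwt[-1L] != bwt[-n])
  run_start <- which(is_start) - 1L
  run_sym <- bwt[is_start]
  run_end <- c(run_start[-1L], n) - 1L
  doc_first <- doc_at_row[run_start + 1L]
  doc_last <- doc_at_row[run_end + 1L]
  r <- length(run_start)

  thr <- integer(r)
  prev_run_of <- rep(-1L, max(text) + 1L)
  for (j in seq_len(r)) {
    c_sym <- run_sym[j]
    p <- prev_run_of[c_sym + 1L]
    if (p >= 0L) {
      e_p <- run_end[p + 1L]
      rows <- (e_p + 1L):run_start[j]
      thr[j] <- rows[which.min(lcp[rows + 1L])]
    }
    prev_run_of[c_sym + 1L] <- j - 1L
  }
  list(n = n, r = r, run_start = run_start, run_sym = run_sym,
       doc_first = doc_first, doc_last = doc_last, thr = thr,
       start_doc = doc_at_row[n])
}

# Naive double-loop evaluation of the peak-weighted vote: position 1 is
# always a peak, position i >= 2 is a peak iff P[i] >= P[i-1]; each peak
# with P > 0 contributes P[i] votes to shred D[i], scaled by the shred's
# complexity weight when the correction is on.
oracle_scores <- function(P, D, shred_ids, C_d, correction) {
  scores <- stats::setNames(numeric(length(shred_ids)),
                            as.character(shred_ids))
  for (i in seq_along(P)) {
    is_peak <- if (i == 1L) TRUE else P[i] >= P[i - 1L]
    if (!is_peak || P[i] <= 0L) next
    j <- match(D[i], shred_ids)
    w <- if (correction) C_d[j] else 1
    scores[j] <- scores[j] + P[i] * w
  }
  scores
}
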