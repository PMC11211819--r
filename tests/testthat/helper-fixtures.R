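# Shared fixtures for the test suite. Everything is generated in code from
# fixed seeds; no binary files are read.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small cached pore models so repeated tests do not regenerate 4^k tables
.fixture_env <- new.env(parent = emptyenv())

fixture_model <- function(k = 4L, seed = 101L) {
  key <- paste0("model_", k, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_pore_model(k, seed = seed)
  }
  .fixture_env[[key]]
}

# a random symbol document over 0:(n_bins-1) wrapped as a bin_seq
rand_doc <- function(len, n_bins, name = "doc", class = "x",
                     polarity = "plain") {
  list(name = name, class = class, polarity = polarity,
       bins = bin_seq(sample(0:(n_bins - 1L), len, replace = TRUE), n_bins))
}

# a small random collection: n_docs documents of random lengths
rand_collection <- function(n_docs = 2L, max_len = 200L, n_bins = 6L,
                            shred_size = 100L) {
  docs <- lapply(seq_len(n_docs), function(i) {
    rand_doc(sample(20:max_len, 1L), n_bins,
             name = paste0("doc", i), class = paste0("class", i))
  })
  shred_collection(docs, shred_size = shred_size)
}

# a tiny end-to-end reference set + index for pipeline tests
fixture_pipeline <- function(seed = 7L, ref_len = 8000L,
                             shred_size = 2000L) {
  key <- paste0("pipe_", seed, "_", ref_len, "_", shred_size)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  model <- fixture_model(6L, seed = 5L)
  set.seed(seed)
  refs <- data.frame(
    name = c("refA", "refB"), class = c("A", "B"),
    polarity = c("positive", "null"),
    seq = c(rand_dna(ref_len), rand_dna(ref_len)),
    stringsAsFactors = FALSE)
  cfg <- binning_config(model)
  coll <- build_reference_collection(refs, model, cfg,
                                     shred_size = shred_size)
  index <- build_index(
    coll, binning = cfg,
    model_stats = list(model_mean = model$model_mean,
                       model_std = model$model_std),
    event_params = event_detection_params())
  out <- list(model = model, refs = refs, cfg = cfg, coll = coll,
              index = index)
  .fixture_env[[key]] <- out
  out
}
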