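test_that("shredding partitions documents into labeled fixed-size pieces", {
  set.seed(41)
  docs <- list(rand_doc(250, 6, name = "a", class = "x"),
               rand_doc(100, 6, name = "b", class = "y"))
  coll <- shred_collection(docs, shred_size = 100)
  # 250 -> 100+100+50, 100 -> 100: four shreds with dense ids
  expect_equal(coll$shreds$shred_id, 0:3)
  expect_equal(coll$shreds$length, c(100L, 100L, 50L, 100L))
  expect_equal(coll$shreds$offset, c(0L, 100L, 200L, 0L))
  expect_equal(coll$shreds$source, c("a", "a", "a", "b"))
  # concatenating a document's shreds reproduces it
  expect_identical(
    unlist(lapply(coll$segments[1:3], `[[`, "symbols")),
    docs[[1]]$bins$symbols)
  expect_equal(coll$class_table$class_name, c("x", "y"))
  expect_equal(coll$class_table$class_id, 0:1)
})

test_that("shredding rejects inconsistent input and skips empty documents", {
  good <- rand_doc(50, 6)
  expect_error(shred_collection(list(), 100), "empty")
  expect_error(shred_collection(list(good), shred_size = 1), "shred_size")
  bad <- rand_doc(50, 4)
  expect_error(shred_collection(list(good, bad), 100), "n_bins")
  empty <- list(name = "e", class = "x", bins = bin_seq(integer(0), 6))
  expect_warning(coll <- shred_collection(list(good, empty), 100),
                 "skipped")
  expect_equal(nrow(coll$shreds), 1L)
})

test_that("reverse-strand segments carry mirrored shred ids", {
  set.seed(42)
  docs <- list(rand_doc(250, 6, name = "a", class = "x"))
  coll <- shred_collection(docs, shred_size = 100)
  rc <- bin_seq(sample(0:5, 240, replace = TRUE), 6)
  coll <- add_reverse_segments(coll, 1, rc)
  rev_segs <- Filter(function(s) s$strand == "-", coll$segments)
  # piece order on the reverse strand sees the forward shreds mirrored
  expect_equal(vapply(rev_segs, `[[`, integer(1), "shred_id"), c(2L, 1L, 0L))
  # pieces tile the reverse sequence completely
  expect_identical(unlist(lapply(rev_segs, `[[`, "symbols")), rc$symbols)
  expect_error(add_reverse_segments(coll, 5, rc), "unknown document")
})

test_that("the index text uses one shared separator and a final sentinel", {
  set.seed(43)
  coll <- rand_collection(n_docs = 2, max_len = 50, shred_size = 30)
  tx <- sigclass:::collection_text(coll)
  n_seg <- length(coll$segments)
  expect_equal(sum(tx$text == 1L), n_seg - 1L)  # shared separator
  expect_equal(sum(tx$text == 0L), 1L)          # unique sentinel, last
  expect_equal(tx$text[length(tx$text)], 0L)
  expect_true(all(tx$text[tx$text > 1L] >= sigclass:::SYM_OFFSET))
  expect_length(tx$doc_of_pos, length(tx$text))
})

test_that("a built index agrees with the brute-force oracle on a small case", {
  set.seed(44)
  coll <- rand_collection(n_docs = 3, max_len = 80, n_bins = 4,
                          shred_size = 40)
  idx <- build_index(coll)
  tx <- sigclass:::collection_text(coll)
  ora <- oracle_index(tx$text, tx$doc_of_pos)
  expect_equal(idx$n, ora$n)
  expect_equal(idx$r, ora$r)
  expect_equal(idx$run_start, ora$run_start)
  expect_equal(idx$run_sym, ora$run_sym)
  expect_equal(idx$doc_first, ora$doc_first)
  expect_equal(idx$doc_last, ora$doc_last)
  expect_equal(idx$thr, ora$thr)
  expect_equal(idx$start_doc, ora$start_doc)
  expect_equal(sum(idx$run_len), idx$n)
})

test_that("streaming PML state resumes exactly across query splits", {
  set.seed(45)
  coll <- rand_collection(n_docs = 2, max_len = 300, shred_size = 150)
  idx <- build_index(coll)
  q <- bin_seq(sample(0:5, 400, replace = TRUE), 6)
  whole <- compute_pmls(idx, q)
  # NOTE: the streaming pass runs right-to-left, so the second half of the
  # query is processed first and its state feeds the first half
  split <- 250L
  right <- compute_pmls(idx, bin_seq(q$symbols[(split + 1):400], 6))
  left <- compute_pmls(idx, bin_seq(q$symbols[1:split], 6),
                       state = right$state)
  expect_identical(c(left$profile$P, right$profile$P), whole$profile$P)
  expect_identical(c(left$profile$D, right$profile$D), whole$profile$D)
  expect_identical(left$state, whole$state)
})

test_that("queries with symbols absent from the text yield zero lengths", {
  docs <- list(list(name = "a", class = "x",
                    bins = bin_seq(rep(c(0L, 1L), 30), 6)))
  idx <- build_index(shred_collection(docs, 100))
  q <- bin_seq(c(0L, 5L, 1L, 5L, 0L), 6)
  p <- compute_pmls(idx, q)$profile
  expect_equal(p$P[c(2, 4)], c(0L, 0L))
  expect_true(all(p$P[c(1, 3, 5)] > 0L))
  expect_error(compute_pmls(idx, bin_seq(0L, 4)), "alphabet")
})

test_that("PMLs never exceed brute-force matching statistics", {
  set.seed(46)
  for (rep in 1:5) {
    coll <- rand_collection(n_docs = 2, max_len = 120, n_bins = 5,
                            shred_size = 60)
    idx <- build_index(coll)
    q <- bin_seq(sample(0:4, 150, replace = TRUE), 5)
    p <- compute_pmls(idx, q)$profile
    ms <- matching_statistics_oracle(q, coll)
    expect_true(all(p$P >= 0L))
    expect_true(all(p$P <= ms))
    expect_true(label_validity_check(p, coll))
  }
})

test_that("an index round-trips losslessly through its directory format", {
  pipe <- fixture_pipeline()
  idx <- pipe$index
  dir <- withr::local_tempdir()
  serialize_index(idx, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_index(dir)
  for (f in c("n", "r", "n_bins", "run_start", "run_sym", "run_len",
              "doc_first", "doc_last", "thr", "C", "sym_runs", "sym_off",
              "sym_cum", "start_doc", "shred_size")) {
    expect_equal(back[[f]], idx[[f]], info = f)
  }
  expect_equal(back$shreds$C_d, idx$shreds$C_d)
  expect_equal(back$class_table, idx$class_table)
  expect_equal(back$binning$s_p, idx$binning$s_p)
  # identical query behavior
  set.seed(47)
  q <- hpc_compress(bin_seq(sample(0:5, 300, replace = TRUE), 6))
  p1 <- compute_pmls(idx, q)$profile
  p2 <- compute_pmls(back, q)$profile
  expect_identical(p1$P, p2$P)
  expect_identical(p1$D, p2$D)
})

test_that("corrupt or mismatched index files are refused", {
  pipe <- fixture_pipeline()
  dir <- withr::local_tempdir()
  serialize_index(pipe$index, dir)
  # flip a byte in one payload file
  f <- file.path(dir, "thresholds.bin")
  bytes <- readBin(f, "raw", file.size(f))
  bytes[5] <- as.raw(bitwXor(as.integer(bytes[5]), 255L))
  writeBin(bytes, f)
  expect_error(load_index(dir), "checksum")
  # version mismatch
  dir2 <- withr::local_tempdir()
  serialize_index(pipe$index, dir2)
  man <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  man$version <- "0.0"
  jsonlite::write_json(man, file.path(dir2, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_index(dir2), "version mismatch")
  expect_error(load_index(withr::local_tempdir()), "manifest")
})
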