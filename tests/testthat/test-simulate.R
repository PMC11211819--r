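test_that("simulation is bitwise reproducible for a fixed seed", {
  model <- fixture_model(4L)
  set.seed(61)
  ref <- rand_dna(3000)
  p <- sim_params(seed = 123L, mean_read_length = 1000)
  r1 <- simulate_read(ref, model, p)
  r2 <- simulate_read(ref, model, p)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth, r2$truth)
  p2 <- sim_params(seed = 124L, mean_read_length = 1000)
  expect_false(identical(simulate_read(ref, model, p2)$samples, r1$samples))
})

test_that("truth labels are consistent with the emitted signal", {
  model <- fixture_model(4L)
  set.seed(62)
  ref <- rand_dna(2000)
  p <- sim_params(seed = 9L, read_length = 800, amp_noise_sd_factor = 0)
  r <- simulate_read(ref, model, p, class_name = "c", source_name = "s")
  expect_equal(r$truth$length, 800L)
  expect_equal(nchar(r$truth$seq), 800L)
  expect_equal(substr(ref, r$truth$start, r$truth$start + 799L), r$truth$seq)
  expect_length(r$truth$kmer_index, length(r$samples))
  # noiseless samples equal the expected level of their originating k-mer
  walk <- if (r$truth$strand == "-") {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(r$truth$seq)))
  } else r$truth$seq
  lv <- expected_signal(model, walk)
  expect_equal(r$samples, lv[r$truth$kmer_index])
  expect_equal(r$truth$class, "c")
  expect_equal(r$truth$source, "s")
})

test_that("stays repeat k-mers and skips omit them in the walk", {
  model <- fixture_model(4L)
  set.seed(63)
  ref <- rand_dna(3000)
  base <- simulate_read(ref, model,
                        sim_params(seed = 5L, read_length = 2000,
                                   dwell_sd = 0))
  stay <- simulate_read(ref, model,
                        sim_params(seed = 5L, read_length = 2000,
                                   dwell_sd = 0, p_stay = 0.4))
  # stays re-emit k-mers: more samples for the same walk, no gaps
  expect_gt(length(stay$samples), length(base$samples))
  ki <- unique(stay$truth$kmer_index)
  expect_identical(ki, seq_len(max(ki)))
  skip <- simulate_read(ref, model,
                        sim_params(seed = 5L, read_length = 2000,
                                   p_skip = 0.4))
  ks <- unique(skip$truth$kmer_index)
  expect_gt(length(setdiff(seq_len(max(ks)), ks)), 0)  # gaps exist
  expect_true(!is.unsorted(ks))
})

test_that("read lengths follow the configured distribution at scale", {
  model <- fixture_model(4L)
  set.seed(64)
  ref <- rand_dna(60000)
  lens <- vapply(1:300, function(i) {
    simulate_read(ref, model,
                  sim_params(seed = i, mean_read_length = 3000))$truth$length
  }, integer(1))
  expect_gt(mean(lens), 1800)
  expect_lt(mean(lens), 4500)
  expect_gt(sd(lens), 800)  # geometric spread, not constant
  strands <- vapply(1:100, function(i) {
    simulate_read(ref, model, sim_params(seed = i))$truth$strand
  }, character(1))
  expect_gt(sum(strands == "+"), 20)
  expect_gt(sum(strands == "-"), 20)
})

test_that("dataset simulation honors the class mixture and truth table", {
  model <- fixture_model(4L)
  set.seed(65)
  refs <- data.frame(name = c("r1", "r2"), class = c("a", "b"),
                     seq = c(rand_dna(4000), rand_dna(4000)),
                     stringsAsFactors = FALSE)
  ds <- simulate_dataset(refs, 40, model,
                         sim_params(seed = 3L, mean_read_length = 500))
  expect_equal(nrow(ds$truth), 40L)
  expect_identical(names(ds$reads), ds$truth$read_id)
  expect_setequal(unique(ds$truth$class), c("a", "b"))
  # skewed mixture
  ds2 <- simulate_dataset(refs, 60, model,
                          sim_params(seed = 4L, mean_read_length = 500),
                          mixture = c(a = 0.9, b = 0.1))
  expect_gt(sum(ds2$truth$class == "a"), 40)
  expect_warning(
    simulate_dataset(refs, 5, model,
                     sim_params(seed = 5L, mean_read_length = 500),
                     mixture = c(a = 2, b = 2)),
    "renormalized")
  expect_error(simulate_dataset(refs, 5, model, mixture = c(a = 1)),
               "missing classes")
  expect_error(simulate_dataset(refs[0, ], 5, model), "empty")
})

test_that("truth tables round-trip through TSV", {
  model <- fixture_model(4L)
  set.seed(66)
  refs <- data.frame(name = "r", class = "c", seq = rand_dna(2000),
                     stringsAsFactors = FALSE)
  ds <- simulate_dataset(refs, 5, model,
                         sim_params(seed = 2L, mean_read_length = 300))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(ds$truth, path)
  expect_equal(read_truth_tsv(path), ds$truth)
})

test_that("evaluation computes confusion metrics from hand-checked joins", {
  report <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    predicted_class = c("pos", "pos", "neg", "neg"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    class = c("pos", "neg", "neg", "pos"),
    length = c(100L, 200L, 300L, 400L),
    stringsAsFactors = FALSE)
  ev <- evaluate_classification(report, truth, positive_classes = "pos")
  expect_equal(ev$accuracy, 0.5)
  expect_equal(ev$accuracy_weighted, (100 + 300) / 1000)
  # tp = r1, fp = r2, fn = r4
  expect_equal(ev$precision, 1 / 2)
  expect_equal(ev$recall, 1 / 2)
  expect_equal(ev$f1, 0.5)
  expect_equal(ev$precision_weighted, 100 / 300)
  expect_equal(ev$recall_weighted, 100 / 500)
  expect_equal(ev$f1_weighted, 2 * (1 / 3) * (1 / 5) / (1 / 3 + 1 / 5))
  expect_equal(as.vector(ev$confusion["pos", "neg"]), 1)
  expect_error(
    evaluate_classification(data.frame(read_id = "zz",
                                       predicted_class = "pos"), truth),
    "missing from truth")
  expect_error(evaluate_classification(report, truth[0, ]), "empty truth")
})
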