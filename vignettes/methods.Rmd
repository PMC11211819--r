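---
title: "Methods: classifying raw nanopore signal with a run-length compressed index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying raw nanopore signal with a run-length compressed index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Problem and model

A nanopore sequencer reports an ionic current trace: as a DNA molecule
translocates through the pore, each k-mer in the pore modulates the current
around a characteristic level. `sigclass` decides, from the raw current
alone and without basecalling, which member of a small reference collection
a read originates from (multi-class mode), or whether it belongs to a
*positive* target versus a *null* background (binary mode, the
adaptive-sampling/host-depletion setting, where the decision can be made on
a growing prefix of the read so the sequencer can eject unwanted
molecules).

The pipeline turns both the signal and the references into strings over a
tiny alphabet and reduces classification to exact substring matching
against a run-length compressed full-text index:

1. **Event detection** segments the raw samples into *events* (one per
   k-mer dwell, ideally) with a rolling Welch t-test.
2. **Normalization** maps the read's scale onto the pore model's scale.
3. **Quantization** bins each event mean into one of `n_bins` picoamp
   ranges, and **homopolymer compression (HPC)** collapses runs of equal
   symbols.
4. References are projected through the same pore model, binned, and
   HPC-compressed, so reads and references live in the same string space.
5. A **run-length BWT index (r-index)** over the shredded reference
   collection supports streaming **pseudo-matching length (PML)** queries.
6. A complexity-weighted **peak vote** over the PML profile produces the
   class decision.

# Event detection

Two rolling Welch t-statistic traces are computed, with a short window
(default 3 samples) and a long window (default 6). A boundary is called at
a local t-statistic maximum exceeding the per-trace threshold (defaults
4.30265 and 2.57058, the constants commonly used for R9.4 segmentation),
with the short detector masking the long one when it is about to fire, and
a minimum peak prominence of 1.0. A variance floor (1e-8) keeps noiseless
plateaus finite. Every sample belongs to exactly one event; an event's mean
current is the arithmetic mean of its samples.

Two error modes matter downstream: *stays* (one k-mer split into several
events) and *skips* (one event spanning several k-mers). Stays produce
repeated near-identical event means, which quantization maps to equal
symbols and HPC removes; this is why both reads and references are
HPC-compressed. Skips lose a symbol and simply truncate matches.

# Normalization

Event means are mapped onto the model scale by
`norm(e) = (e - mu) / sd * model_std + model_mean`, where `model_mean` and
`model_std` are the mean and (population) standard deviation of all pore
model levels, and `mu`, `sd` are the read's own statistics. Two design
decisions here:

* **Duration weighting.** `mu` and `sd` are computed over event means
  weighted by event dwell — i.e. they are the statistics of the denoised
  staircase signal in the sample domain. This makes the scale invariant to
  how a constant stretch happens to be segmented: merging or splitting a
  plateau does not change the statistics. With unweighted statistics, an
  undetectable boundary between two equal-level k-mers (which no detector
  can find — there is no signal) would perturb the read's scale.
* **Incremental state.** The statistics are maintained with weighted
  Welford/Chan merging, so successive chunks of one read share one state.
  Statistics are never shared across reads.

References are projected to their expected current trace and standardized
onto the same `(model_mean, model_std)` scale before binning. Because both
sides undergo the same affine family, a noiseless, constant-dwell read
processed through the full pipeline reproduces `reference_to_binseq` of its
source sequence *exactly* — the keystone property the test suite verifies.
With variable dwell the duration-weighted read statistics differ from the
per-position reference statistics by O(sd/sqrt(n)), so near-boundary values
can land in adjacent bins; classification tolerates this, exactness does
not.

# Quantization

The model's level range `[min_p, max_p]` is divided into `n_bins` (default
6) equal-width bins; values below/above the range clamp to the extreme
bins, interior bins are half-open with a closed top bin. Six bins is coarse
enough that amplitude noise (default 2 pA, against a typical level spread
of tens of pA) usually stays within a bin, yet fine enough that exact
matches of a few dozen symbols are specific.

# Reference index

Each reference is split at ambiguity codes, projected, binned, and
HPC-compressed, on both strands by default (nanopore reads arrive from
either strand; the reverse-complement projection is *not* the reverse of
the forward projection, so it is indexed explicitly). Documents are
*shredded* into fixed-size pieces (default 100 000 symbols) so a match
localizes to a reference region; reverse-strand text is cut at
proportionally mirrored positions and assigned the mirrored shred ids, so
both strands of one region vote together.

The text is the concatenation of all shreds separated by a single shared
separator symbol, terminated by a unique sentinel. A shared separator —
rather than one distinct terminator per shred — keeps the alphabet fixed,
which is what makes the number of BWT runs `r` insensitive to content
repetition: indexing t copies of the same shred set grows `r` by a small
constant while `n` grows t-fold (verified in the acceptance suite). The
separator can never be matched by a query (queries use only bin symbols),
so it partitions matches without polluting them.

From the suffix array (prefix doubling, O(n log² n), adequate at desk
scale) the index keeps only O(r) structures: the run-length encoded BWT,
MONI-style *thresholds* (for each pair of consecutive same-symbol runs,
the row of minimum LCP between them — the optimal boundary for deciding
which run to jump to), and a *sampled document array* (the shred label at
the first and last row of every run). The suffix array and LCP are
discarded.

# Streaming PML queries

A query is processed right-to-left, maintaining the backward-search row
interval of the current match, one concrete row inside it (always a row
whose label is known), the match length, and the shred label:

* If the interval can be extended with the next symbol (two O(log r) rank
  computations), the match grows by one. If the tracked row does not carry
  the symbol, the matcher hops to the nearest same-symbol run boundary
  *inside* the interval — a sampled row, so the label is picked up there —
  with the threshold breaking ties between the two candidate sides.
* If no extension exists anywhere, the matcher jumps to the nearest run of
  the wanted symbol in the threshold direction and the length resets.

`P[i]` is therefore the length of the longest uninterrupted backward match
ending at position i — a matching statistic truncated at mismatch resets —
and `D[i]` the shred holding it. Two exact properties follow: `P[i]` never
exceeds the true matching statistic, and a query equal to a text substring
yields the full descending profile `[m, m-1, ..., 1]`. The (row, length,
label, interval) state is returned to the caller, so successive chunks of
one read resume exactly; in chunk mode the package reprocesses the growing
prefix so that normalization also reflects everything seen so far, making
the final chunk decision identical to the whole-read decision.

# Classification

Within one exact match the PML decrements by one per position, so positions
where it fails to decrease are *peaks* — starts of new matches, the natural
vote unit (counting every position would weight a match quadratically).
Each peak contributes `P[i]` votes to shred `D[i]`, weighted by the shred's
normalized substring complexity `C_d` (the maximum over k of distinct
k-substrings divided by k, k capped at 12, normalized to (0, 1] across the
collection) to down-weight low-complexity regions that attract spurious
matches.

Multi-class mode predicts the class of the argmax shred (ties toward the
lowest id, flagged). Binary mode compares the best positive-class shred
score to the best null-class score; the read is called positive iff this
*spike ratio* strictly exceeds the threshold (default 1.0, suited to
roughly balanced mixtures). For skewed mixtures, `calibrate_threshold()`
picks the threshold from burn-in reads and an expected positive fraction
(midpoint between the m-th and (m+1)-th largest observed ratio).

# Simulator

The simulator exists to exercise the pipeline end-to-end with known truth,
not to model pore physics. Per read: a reference substring (uniform start
and strand; geometric length, mean 10 000 bases, or pinned), a k-mer walk
with optional stay (re-emit) and skip (advance two) errors, a
truncated-normal dwell per event (mean 9, sd 8, minimum 1 sample —
roughly 4 kHz sampling at 450 b/s), the pore-model level per k-mer, and
Gaussian amplitude noise (default sd 2.0 pA). Fixed seeds give bitwise
reproducibility; dataset-level seeds derive per-read seeds. Known limits:
no low-frequency drift, no heavy-tailed noise, no adapter/barcode signal,
dwell independent of sequence context.

# Problem sizes and costs

Designed for desk scale: references up to a few hundred kb (suffix-array
construction is the O(n log² n) bottleneck; ~170 k text symbols for two
50 kb references, both strands, build ~5 s), reads of tens of thousands of
samples (event detection is linear; PML steps are O(log r)). Classifying
200 reads (~20 M samples) against that index takes ~15 s single-threaded.
The serialized index stores O(r) integers plus a JSON manifest with
checksums.

# Worked example

```{r, eval = FALSE}
library(sigclass)

model <- generate_pore_model(6, seed = 1)
refs <- data.frame(
  name = c("target", "background"),
  class = c("target", "background"),
  polarity = c("positive", "null"),
  seq = c(paste(sample(c("A","C","G","T"), 50000, TRUE), collapse = ""),
          paste(sample(c("A","C","G","T"), 50000, TRUE), collapse = "")))

cfg <- binning_config(model)
coll <- build_reference_collection(refs, model, cfg)
index <- build_index(coll, binning = cfg,
                     model_stats = list(model_mean = model$model_mean,
                                        model_std = model$model_std))

ds <- simulate_dataset(refs, 50, model, sim_params(seed = 42))
report <- classify_reads(index, ds$reads, mode = "binary")
evaluate_classification(report, ds$truth, positive_classes = "target")
```

The file-based interface (`cmd_build()`, `cmd_simulate()`,
`cmd_classify()`, `cmd_evaluate()`, and the `inst/cli/sigclass.R` script)
wraps the same calls for shell pipelines.
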