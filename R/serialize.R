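INDEX_FORMAT_VERSION <- "1.0"

write_int_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(x), con, size = 4L, endian = "little")
  invisible(path)
}

read_int_bin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(out) != n) stop("truncated array file: ", basename(path))
  out
}

write_dbl_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

read_dbl_bin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(out) != n) stop("truncated array file: ", basename(path))
  out
}

#' Serialize a reference index to a directory
#'
#' Layout: `manifest.json` (scalars, class table, shred table, checksums),
#' `bwt.rle` (int32 (symbol, run length) pairs), `thresholds.bin` (int32 per
#' run), `docs.bin` (int32 first-row labels then last-row labels), and
#' `complexity.bin` (doubles: raw complexity then normalized weight per
#' shred). All arrays are little-endian. The manifest reports `n`, `r`, and
#' `n/r` for inspection.
#'
#' @param index a `ref_index`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
serialize_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    "bwt.rle" = function(p)
      write_int_bin(rbind(index$run_sym, index$run_len), p),
    "thresholds.bin" = function(p) write_int_bin(index$thr, p),
    "docs.bin" = function(p)
      write_int_bin(c(index$doc_first, index$doc_last), p),
    "complexity.bin" = function(p)
      write_dbl_bin(c(index$shreds$complexity_raw, index$shreds$C_d), p))
  for (f in names(files)) files[[f]](file.path(dir, f))
  checksums <- vapply(names(files), function(f) {
    unname(tools::md5sum(file.path(dir, f)))
  }, character(1L))
  manifest <- list(
    version = INDEX_FORMAT_VERSION,
    n = index$n, r = index$r, n_over_r = index$n / index$r,
    n_bins = index$n_bins, shred_size = index$shred_size,
    start_doc = index$start_doc,
    complexity_method = index$complexity_method,
    class_table = index$class_table,
    shreds = index$shreds[, c("shred_id", "class_id", "source", "offset",
                              "length")],
    binning = index$binning[c("n_bins", "min_p", "max_p", "s_p")],
    model_stats = index$model_stats,
    event_params = unclass(index$event_params),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a serialized reference index
#'
#' Validates the manifest version and per-file checksums, then rebuilds the
#' in-memory rank structures. Lossless inverse of [serialize_index()].
#'
#' @param dir index directory.
#' @return a `ref_index`.
#' @export
load_index <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(man$version, INDEX_FORMAT_VERSION)) {
    stop("index format version mismatch: found ", man$version,
         ", expected ", INDEX_FORMAT_VERSION)
  }
  for (f in names(man$checksums)) {
    found <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(found, man$checksums[[f]])) {
      stop("checksum mismatch for ", f, " (corrupt or truncated index)")
    }
  }
  r <- man$r
  rle2 <- read_int_bin(file.path(dir, "bwt.rle"), 2L * r)
  run_sym <- rle2[seq(1L, 2L * r, by = 2L)]
  run_len <- rle2[seq(2L, 2L * r, by = 2L)]
  run_start <- as.integer(c(0L, cumsum(run_len))[seq_len(r)])
  if (sum(run_len) != man$n) stop("run lengths do not sum to n")
  thr <- read_int_bin(file.path(dir, "thresholds.bin"), r)
  docs2 <- read_int_bin(file.path(dir, "docs.bin"), 2L * r)
  S <- nrow(man$shreds)
  cx <- read_dbl_bin(file.path(dir, "complexity.bin"), 2L * S)
  shreds <- as.data.frame(man$shreds)
  shreds$complexity_raw <- cx[seq_len(S)]
  shreds$C_d <- cx[S + seq_len(S)]
  n_sym <- man$n_bins + SYM_OFFSET
  rk <- prepare_rank(run_sym, run_len, n_sym)
  ev <- man$event_params
  if (!is.null(ev)) class(ev) <- "event_detection_params"
  bn <- man$binning
  if (!is.null(bn) && !is.null(bn$n_bins)) class(bn) <- "binning_config"
  structure(list(
    n = man$n, r = r, n_bins = man$n_bins,
    run_start = run_start, run_sym = run_sym, run_len = run_len,
    doc_first = docs2[seq_len(r)], doc_last = docs2[r + seq_len(r)],
    thr = thr,
    C = rk$C, sym_runs = rk$sym_runs, sym_off = rk$sym_off,
    sym_cum = rk$sym_cum,
    start_doc = man$start_doc,
    shreds = shreds, class_table = as.data.frame(man$class_table),
    shred_size = man$shred_size,
    complexity_method = man$complexity_method,
    binning = bn, model_stats = man$model_stats,
    event_params = ev),
    class = "ref_index")
}
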