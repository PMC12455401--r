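#' Filter paired FASTQ files by labeled read IDs
#'
#' Removal operates at read-pair granularity: if a pair's normalized ID is
#' in the label set, both mates go to the removed output, otherwise both
#' are kept. Record order and record bytes are preserved, so kept plus
#' removed, re-interleaved in input order, reconstruct the input exactly.
#'
#' @name fastq_filtering
NULL

# Read a FASTQ file as raw 4-line records. Filtering must not re-encode
# records (qualities, header comments, wrapping), so this reader keeps the
# original lines verbatim; sequence-level access (kmer_classifier) goes
# through Biostrings instead. Wrapped (multi-line) FASTQ is rejected.
read_fastq_records <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop_hf("FASTQ '%s': line count %d is not a multiple of 4", path,
            length(lines), class = "hostfilter_format_error")
  if (length(lines) == 0L)
    return(list(id = character(0), seq = character(0),
                lines = lines, n = 0L))
  idx <- seq(1L, length(lines), by = 4L)
  if (any(!startsWith(lines[idx], "@")) || any(!startsWith(lines[idx + 2L], "+")))
    stop_hf("FASTQ '%s': malformed record structure (wrapped FASTQ is not supported)",
            path, class = "hostfilter_format_error")
  list(id = lines[idx], seq = lines[idx + 1L], lines = lines,
       n = length(idx))
}

write_fastq_lines <- function(lines, path, gz) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Indices into the flat line vector for records `keep` (logical over records).
record_lines <- function(keep) {
  if (!any(keep)) return(integer(0))
  as.vector(vapply(which(keep), function(i) (4L * (i - 1L) + 1L):(4L * i),
                   integer(4)))
}

#' Remove labeled read (pairs) from FASTQ files
#'
#' @param labels a [label_set()] (typically the merged set).
#' @param r1 path to R1 FASTQ(.gz).
#' @param r2 optional path to mate R2 FASTQ(.gz); must be synchronized
#'   with `r1`.
#' @param out_dir output directory (created if needed). Kept files are
#'   written as `kept_<basename>`, removed files (only when
#'   `emit_removed`) as `removed_<basename>`. Output compression mirrors
#'   the input (gzip detected by magic bytes).
#' @param emit_removed write the removed reads too?
#' @return a list: `counts` (input / kept / removed pair counts and the
#'   number of labeled IDs not present in the FASTQ), `kept` and `removed`
#'   (output paths), invisibly.
#' @export
filter_fastq <- function(labels, r1, r2 = NULL, out_dir = ".",
                         emit_removed = FALSE) {
  stopifnot(inherits(labels, "label_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- read_fastq_records(r1)
  ids <- normalize_id_allow_empty(f1$id)
  f2 <- NULL
  if (!is.null(r2)) {
    f2 <- read_fastq_records(r2)
    if (f2$n != f1$n)
      stop_hf("mate files differ in record count (%d vs %d)", f1$n, f2$n,
              class = "hostfilter_pairing_error")
    ids2 <- normalize_id_allow_empty(f2$id)
    if (f1$n > 0L && !identical(ids, ids2)) {
      i <- which(ids != ids2)[1]
      stop_hf("mate ID mismatch at record %d: '%s' vs '%s'", i, ids[i], ids2[i],
              class = "hostfilter_pairing_error")
    }
  }
  remove <- ids %in% labels$ids
  unmatched <- setdiff(labels$ids, ids)

  emit <- function(f, in_path) {
    gz <- is_gzipped(in_path)
    base <- sub("\\.gz$", "", basename(in_path))
    if (gz) base <- paste0(base, ".gz")
    kept_path <- file.path(out_dir, paste0("kept_", base))
    write_fastq_lines(f$lines[record_lines(!remove)], kept_path, gz)
    removed_path <- NULL
    if (emit_removed) {
      removed_path <- file.path(out_dir, paste0("removed_", base))
      write_fastq_lines(f$lines[record_lines(remove)], removed_path, gz)
    }
    list(kept = kept_path, removed = removed_path)
  }
  p1 <- emit(f1, r1)
  p2 <- if (!is.null(f2)) emit(f2, r2) else NULL

  res <- list(
    counts = list(input = f1$n,
                  kept = sum(!remove),
                  removed = sum(remove),
                  unmatched_labels = length(unmatched)),
    kept = c(p1$kept, p2$kept),
    removed = c(p1$removed, p2$removed))
  invisible(res)
}
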