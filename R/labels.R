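#' Label sets of read-pair IDs
#'
#' A `label_set` names the read pairs one classifier flagged as
#' contamination for one sample. IDs are stored normalized so that
#' Kraken2-side and FASTQ-side identifiers compare equal.
#'
#' @name label_sets
NULL

#' Normalize a read (pair) identifier
#'
#' Takes the token before the first whitespace, strips one leading `@` and
#' one trailing `/1` or `/2` mate suffix. The same rule is applied on the
#' classifier side and the FASTQ side, so IDs from both worlds match.
#'
#' @param raw character vector of raw identifiers (FASTQ header lines are
#'   accepted).
#' @return character vector of normalized IDs.
#' @examples
#' normalize_id("@SRR1.7 7 length=150")  # "SRR1.7"
#' normalize_id("read12/2")              # "read12"
#' @export
normalize_id <- function(raw) {
  out <- normalize_id_allow_empty(raw)
  if (any(!nzchar(out)))
    stop_hf("read ID empty after normalization (raw: '%s')",
            raw[!nzchar(out)][1], class = "hostfilter_format_error")
  out
}

normalize_id_allow_empty <- function(raw) {
  out <- sub("[ \t].*$", "", raw)
  out <- sub("^@", "", out)
  sub("/[12]$", "", out)
}

#' Construct a label set
#'
#' @param ids character vector of read-pair IDs (normalized with
#'   [normalize_id()]; duplicates are dropped).
#' @param sample sample name.
#' @param tool name of the classifier that produced the labels.
#' @return an object of class `label_set` with fields `sample`, `tool`,
#'   `ids` (sorted unique character vector).
#' @export
label_set <- function(ids, sample = "sample", tool = "unknown") {
  ids <- unique(as.character(ids))
  if (any(grepl("[ \t]", ids)) || any(grepl("/[12]$", ids)))
    ids <- normalize_id(ids)
  structure(list(sample = sample, tool = tool, ids = sort(ids)),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: sample=%s tool=%s, %d read pair(s)\n",
              x$sample, x$tool, length(x$ids)))
  invisible(x)
}

#' @export
length.label_set <- function(x) length(x$ids)

#' Union-merge label sets from multiple classifiers
#'
#' The union of the IDs labeled by the individual classifiers is the
#' final contamination call when several classifiers are run.
#'
#' @param sets list of [label_set()] objects for the same sample.
#' @return a [label_set()] with `tool = "merged"` and the ID union.
#' @export
merge_labels <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "label_set")))
  samples <- unique(vapply(sets, `[[`, character(1), "sample"))
  if (length(samples) != 1L)
    stop_hf("cannot merge label sets from different samples: %s",
            paste(samples, collapse = ", "), class = "hostfilter_usage_error")
  label_set(unique(unlist(lapply(sets, `[[`, "ids"), use.names = FALSE)),
            sample = samples, tool = "merged")
}

#' Read / write a label list (one normalized ID per line)
#'
#' @param path plain-text file path.
#' @param sample,tool metadata attached to the read set.
#' @return `read_label_list`: a [label_set()]. `write_label_list`:
#'   invisibly, the path.
#' @export
read_label_list <- function(path, sample = "sample", tool = "unknown") {
  ids <- readLines(path)
  label_set(ids[nzchar(ids)], sample = sample, tool = tool)
}

#' @rdname read_label_list
#' @param labels a [label_set()] to write.
#' @export
write_label_list <- function(labels, path) {
  stopifnot(inherits(labels, "label_set"))
  writeLines(labels$ids, path)
  invisible(path)
}

#' Summarize labeling effort per sample and tool
#'
#' One row per (sample, tool) with the labeled read-pair count and its
#' fraction of the sample's input pairs.
#'
#' @param sets list of [label_set()] objects.
#' @param totals named numeric vector: sample name -> input read-pair
#'   count.
#' @return data.frame with columns `sample`, `tool`, `labeled`,
#'   `fraction`.
#' @export
summarize_labels <- function(sets, totals) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L)
    return(data.frame(sample = character(0), tool = character(0),
                      labeled = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE))
  stopifnot(all(vapply(sets, inherits, logical(1), "label_set")))
  sample <- vapply(sets, `[[`, character(1), "sample")
  missing <- setdiff(sample, names(totals))
  if (length(missing) > 0L)
    stop_hf("no input pair total for sample(s): %s",
            paste(missing, collapse = ", "), class = "hostfilter_usage_error")
  labeled <- vapply(sets, function(s) length(s$ids), integer(1))
  data.frame(sample = sample,
             tool = vapply(sets, `[[`, character(1), "tool"),
             labeled = labeled,
             fraction = labeled / as.numeric(totals[sample]),
             stringsAsFactors = FALSE)
}

#' Write a labeling summary as TSV
#'
#' @param summary data.frame from [summarize_labels()].
#' @param path output path.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
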