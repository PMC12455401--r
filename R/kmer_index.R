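#' Exact canonical k-mer membership classifier
#'
#' Builds the set of canonical k-mers (lexicographic minimum of a k-mer
#' and its reverse complement, A<C<G<T) of a reference FASTA and labels
#' any read (pair) sharing at least one k-mer with the reference — the
#' labeling behaviour of bbduk-style screening. Membership is exact: no
#' mismatch neighbourhoods, no masking. The default k is 27.
#'
#' @name kmer_classifier
NULL

#' Build a canonical k-mer index from a reference FASTA
#'
#' Every length-k window of every record contributes its canonical form;
#' windows containing non-ACGT characters are skipped and sequence case is
#' ignored. Both strands of the reference collapse to one entry per k-mer.
#'
#' @param reference path to a (multi-record, possibly line-wrapped) FASTA
#'   file, a `Biostrings::DNAStringSet`, or a named character vector of
#'   sequences.
#' @param k k-mer length in bases (default 27, the classifier's standard
#'   screening size); k <= 31 is guaranteed supported.
#' @return an object of class `kmer_index`: list with `k`, `kmers`
#'   (character vector of canonical k-mers) and `source`.
#' @export
build_kmer_index <- function(reference, k = 27L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  src <- "in-memory"
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    src <- reference
    reference <- tryCatch(Biostrings::readDNAStringSet(reference),
                          error = function(e)
                            stop_hf("malformed FASTA '%s': %s", src,
                                    conditionMessage(e),
                                    class = "hostfilter_format_error"))
    if (length(reference) == 0L)
      stop_hf("FASTA '%s' contains no records", src,
              class = "hostfilter_format_error")
  }
  seqs <- toupper(as.character(reference))
  kmers <- unique(unlist(lapply(seqs, valid_kmers, k = k), use.names = FALSE))
  structure(list(k = k, kmers = canonical_kmer(kmers), source = src),
            class = "kmer_index")
}

# All ACGT-only k-windows of one sequence (not canonicalized).
valid_kmers <- function(seq, k) {
  w <- seq_windows(seq, k)
  w[acgt_window_mask(seq, k)]
}

#' Canonical form of k-mers
#'
#' @param kmers character vector of ACGT k-mers (upper case).
#' @return the lexicographically smaller of each k-mer and its reverse
#'   complement.
#' @export
canonical_kmer <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- reverse_complement(kmers)
  swap <- rc < kmers
  kmers[swap] <- rc[swap]
  unique(kmers)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d canonical k-mers (source: %s)\n",
              x$k, length(x$kmers), x$source))
  invisible(x)
}

#' Classify one read against a k-mer index
#'
#' @param index a [build_kmer_index()] object.
#' @param sequence read sequence (character scalar; case-insensitive).
#' @return `TRUE` iff at least one ACGT-only window of the read, in
#'   canonical form, is present in the index. Reads shorter than k never
#'   hit.
#' @export
classify_read <- function(index, sequence) {
  stopifnot(inherits(index, "kmer_index"))
  w <- valid_kmers(toupper(sequence), index$k)
  if (length(w) == 0L) return(FALSE)
  any(canonical_kmer(w) %in% index$kmers)
}

#' Label FASTQ read (pairs) sharing a k-mer with the reference
#'
#' A pair is labeled when either mate hits the index. Mate streams must be
#' synchronized: same record count and, after [normalize_id()], identical
#' IDs in identical order.
#'
#' @param index a [build_kmer_index()] object.
#' @param r1 path to the R1 FASTQ(.gz) file.
#' @param r2 optional path to the mate R2 FASTQ(.gz) file.
#' @param sample sample name recorded in the returned label set.
#' @return a [label_set()] with `tool = "kmer_classifier"`.
#' @export
label_fastq <- function(index, r1, r2 = NULL, sample = "sample") {
  stopifnot(inherits(index, "kmer_index"))
  f1 <- read_fastq_records(r1)
  ids <- normalize_id_allow_empty(f1$id)
  hit <- vapply(f1$seq, classify_read, logical(1), index = index)
  if (!is.null(r2)) {
    f2 <- read_fastq_records(r2)
    if (length(f2$id) != length(f1$id))
      stop_hf("mate files differ in record count (%d vs %d)",
              length(f1$id), length(f2$id), class = "hostfilter_pairing_error")
    ids2 <- normalize_id_allow_empty(f2$id)
    if (!identical(ids, ids2)) {
      i <- which(ids != ids2)[1]
      stop_hf("mate ID mismatch at record %d: '%s' vs '%s'", i, ids[i], ids2[i],
              class = "hostfilter_pairing_error")
    }
    hit <- hit | vapply(f2$seq, classify_read, logical(1), index = index)
  }
  label_set(unique(ids[hit]), sample = sample, tool = "kmer_classifier")
}
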