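#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over a character vector. Non-ACGT
#' characters are complemented by IUPAC rules (via Biostrings).
#'
#' @param x character vector of DNA sequences (case-insensitive).
#' @return character vector of reverse complements, upper case.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Open a connection that transparently handles gzip, detected by magic
# bytes (1f 8b), never by file extension.
open_maybe_gz <- function(path, mode = "rt") {
  if (is_gzipped(path)) gzfile(path, mode) else file(path, mode)
}

is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Split sequence into all length-k windows; returns character(0) when the
# sequence is shorter than k.
seq_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Logical mask over windows: TRUE where the window contains only A/C/G/T.
# Uses a cumulative count of offending characters so the scan is O(n).
acgt_window_mask <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(logical(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- cumsum(!(chars %in% c("A", "C", "G", "T")))
  start <- 1:(n - k + 1L)
  end <- k:n
  (bad[end] - c(0L, bad)[start]) == 0L
}

stop_hf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hostfilter_error")))
}
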