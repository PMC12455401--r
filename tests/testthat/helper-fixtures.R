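# Shared fixtures and independent oracles.

# Small hand-drawn taxonomy:
#   1 (root)
#   +-- 10 "Left clade"
#   |    +-- 11 "Left A"   +-- 12 "Left B"
#   |         +-- 111, 112      +-- 121, 122
#   +-- 9606 "Homo sapiens"
fixture_tree <- function() {
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "10\t|\t1\t|\tclade\t|",
    "11\t|\t10\t|\tgenus\t|",
    "12\t|\t10\t|\tgenus\t|",
    "111\t|\t11\t|\tspecies\t|",
    "112\t|\t11\t|\tspecies\t|",
    "121\t|\t12\t|\tspecies\t|",
    "122\t|\t12\t|\tspecies\t|",
    "9606\t|\t1\t|\tspecies\t|")
  names <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "10\t|\tLeft clade\t|\t\t|\tscientific name\t|",
    "9606\t|\tHomo sapiens\t|\t\t|\tscientific name\t|",
    "9606\t|\thuman\t|\t\t|\tcommon name\t|",
    "111\t|\tSpecies one\t|\t\t|\tscientific name\t|")
  parse_taxdump(nodes, names)
}

# Random DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Brute-force oracle: does `read` share any length-k substring with
# `reference`, on either strand? Enumerates all substrings of both.
bf_shares_kmer <- function(reference, read, k) {
  subs <- function(s) {
    n <- nchar(s)
    if (n < k) character(0) else substring(s, 1:(n - k + 1), k:n)
  }
  ref_k <- unique(c(subs(reference), subs(reverse_complement(reference))))
  read_k <- unique(c(subs(read), subs(reverse_complement(read))))
  ref_k <- ref_k[!grepl("[^ACGT]", ref_k)]
  read_k <- read_k[!grepl("[^ACGT]", read_k)]
  length(intersect(ref_k, read_k)) > 0
}

# Independent per-line tally oracle: recount T/O/U directly from the raw
# Kraken2 token string, bypassing parse_kraken_line/kmer_tally.
bf_tally_from_line <- function(line, target) {
  field5 <- strsplit(line, "\t", fixed = TRUE)[[1]][5]
  toks <- strsplit(gsub("\\|:\\|", " ", field5), " +")[[1]]
  toks <- toks[nzchar(toks)]
  out <- c(T = 0, O = 0, U = 0)
  for (tok in toks) {
    p <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (p[1] == "A") next
    n <- as.integer(p[2])
    if (p[1] == "0") out["U"] <- out["U"] + n
    else if (as.integer(p[1]) %in% target) out["T"] <- out["T"] + n
    else out["O"] <- out["O"] + n
  }
  out
}

# Closed-form Pearson chi-squared on a 2x2 table.
bf_chi2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Random Kraken2-format record over taxa of fixture_tree(), for property
# sweeps; returns the raw line.
random_kraken_line <- function(id) {
  taxa <- c("0", "A", "1", "10", "11", "111", "112", "121", "9606")
  mate <- function() {
    n <- sample(1:6, 1)
    paste(sprintf("%s:%d", sample(taxa, n, replace = TRUE),
                  sample(1:20, n, replace = TRUE)), collapse = " ")
  }
  sprintf("C\t%s\t9606\t100|100\t%s |:| %s", id, mate(), mate())
}

# Write a tiny FASTQ with fixed "I" qualities; ids are raw header tokens.
write_test_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                           vapply(seqs, function(s) strrep("I", nchar(s)), "")))
  writeLines(lines, path)
  path
}
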