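#' Kraken2 per-read output and the three-condition cutoff model
#'
#' Kraken2's standard per-read output is a 5-column TSV: classified flag
#' (`C`/`U`), read ID, consensus taxon, read length(s), and the k-mer LCA
#' mapping string — space-separated `taxid:count` runs, with `|:|`
#' separating the two mates of a pair and `A` marking k-mers spanning
#' ambiguous bases. The labeling model tallies, per read pair, the k-mers
#' assigned within the target subtree (T), to any other classified taxon
#' (O), and unclassified (U), and flags the pair as contamination only if
#' all three conditions hold:
#'
#' 1. `T > cutoff_tax2filter` (an absolute k-mer count),
#' 2. `T / (O + T) > cutoff_tax2keep` (a ratio in \[0,1\]),
#' 3. `T / (U + T) > cutoff_unclassified` (a ratio in \[0,1\]).
#'
#' With all cutoffs at 0 a pair is labeled exactly when at least one k-mer
#' maps into the target subtree, regardless of matches to other taxa.
#'
#' @name kraken_model
NULL

#' Parse one line of Kraken2 standard per-read output
#'
#' @param line a single 5-column tab-separated line.
#' @param line_number optional line number used in error messages.
#' @return an object of class `kraken_record`: list with `classified`
#'   (logical), `read_id`, `consensus_taxon` (integer), `lengths` (integer
#'   vector, one per mate), and `kmer_runs` — a list of one or two
#'   data.frames with columns `assignment` (character: a taxon ID, `"0"`
#'   for unclassified, `"A"` for ambiguous) and `count` (integer).
#' @examples
#' rec <- parse_kraken_line("C\tr1\t9606\t150|150\t9606:3 0:2 |:| A:1 9606:4")
#' rec$kmer_runs[[2]]
#' @export
parse_kraken_line <- function(line, line_number = NA_integer_) {
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 5L)
    stop_hf("expected 5 tab-separated columns, got %d%s",
            length(fields), where, class = "hostfilter_parse_error")
  if (!(fields[1] %in% c("C", "U")))
    stop_hf("classified flag must be C or U, got '%s'%s", fields[1], where,
            class = "hostfilter_parse_error")
  lengths <- suppressWarnings(as.integer(strsplit(fields[4], "|", fixed = TRUE)[[1]]))
  if (anyNA(lengths))
    stop_hf("malformed length field '%s'%s", fields[4], where,
            class = "hostfilter_parse_error")

  mate_strings <- strsplit(fields[5], "|:|", fixed = TRUE)[[1]]
  mate_strings <- trimws(mate_strings)
  runs <- lapply(mate_strings, function(s) {
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L)
      return(data.frame(assignment = character(0), count = integer(0),
                        stringsAsFactors = FALSE))
    parts <- strsplit(toks, ":", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad))
      stop_hf("malformed k-mer token '%s'%s", toks[bad][1], where,
              class = "hostfilter_parse_error")
    assignment <- vapply(parts, `[`, character(1), 1L)
    count <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
    ok_assign <- assignment == "A" | grepl("^[0-9]+$", assignment)
    if (any(!ok_assign) || anyNA(count) || any(count <= 0L))
      stop_hf("malformed k-mer token '%s'%s",
              toks[!ok_assign | is.na(count) | count <= 0L][1], where,
              class = "hostfilter_parse_error")
    data.frame(assignment = assignment, count = count, stringsAsFactors = FALSE)
  })
  if (!(length(runs) %in% c(1L, 2L)))
    stop_hf("expected 1 or 2 mate k-mer lists, got %d%s", length(runs), where,
            class = "hostfilter_parse_error")

  structure(list(classified = fields[1] == "C",
                 read_id = fields[2],
                 consensus_taxon = as.integer(fields[3]),
                 lengths = lengths,
                 kmer_runs = runs),
            class = "kraken_record")
}

#' Read a Kraken2 standard output file
#'
#' @param path path to a (optionally gzipped) 5-column Kraken2 per-read
#'   output file, or a character vector of lines.
#' @return list of [kraken_record][parse_kraken_line] objects.
#' @export
read_kraken_output <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    con <- open_maybe_gz(path)
    on.exit(close(con))
    readLines(con)
  } else path
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) parse_kraken_line(lines[i], i))
}

#' Cutoffs of the k-mer labeling model
#'
#' @param cutoff_tax2filter minimum count of target-subtree k-mers
#'   (condition is strict: `T > cutoff`). Default 0 labels any pair with
#'   at least one target k-mer.
#' @param cutoff_tax2keep ratio threshold in \[0,1\] for
#'   `T / (O + T)` where O counts k-mers assigned to non-target taxa.
#' @param cutoff_unclassified ratio threshold in \[0,1\] for
#'   `T / (U + T)` where U counts unclassified k-mers.
#' @return an object of class `model_cutoffs`.
#' @export
model_cutoffs <- function(cutoff_tax2filter = 0,
                          cutoff_tax2keep = 0,
                          cutoff_unclassified = 0) {
  stopifnot(cutoff_tax2filter >= 0,
            cutoff_tax2keep >= 0, cutoff_tax2keep <= 1,
            cutoff_unclassified >= 0, cutoff_unclassified <= 1)
  structure(list(cutoff_tax2filter = cutoff_tax2filter,
                 cutoff_tax2keep = cutoff_tax2keep,
                 cutoff_unclassified = cutoff_unclassified),
            class = "model_cutoffs")
}

#' Tally target / other / unclassified k-mers of a read (pair)
#'
#' Counts are pooled across both mates; `A` (ambiguous-base) k-mers are
#' excluded from all three counts. K-mers assigned to taxa outside the
#' target set — including ancestors of the target such as the root — count
#' as O.
#'
#' @param record a [kraken_record][parse_kraken_line].
#' @param target integer vector of taxon IDs (the target subtree, from
#'   [subtree()]).
#' @return an object of class `kmer_tally`: list with integer counts
#'   `T`, `O`, `U`.
#' @export
kmer_tally <- function(record, target) {
  stopifnot(inherits(record, "kraken_record"))
  target_chr <- as.character(as.integer(target))
  T_ <- O_ <- U_ <- 0L
  for (runs in record$kmer_runs) {
    a <- runs$assignment
    n <- runs$count
    amb <- a == "A"
    unc <- a == "0"
    tgt <- !amb & !unc & (a %in% target_chr)
    oth <- !amb & !unc & !tgt
    T_ <- T_ + sum(n[tgt])
    O_ <- O_ + sum(n[oth])
    U_ <- U_ + sum(n[unc])
  }
  structure(list(T = as.integer(T_), O = as.integer(O_), U = as.integer(U_)),
            class = "kmer_tally")
}

#' Apply the three cutoff conditions to a tally
#'
#' All three inequalities are strict; with `T = 0` condition (i) already
#' fails for any cutoff >= 0, so the ratios are never formed on an empty
#' tally.
#'
#' @param tally a [kmer_tally()].
#' @param cutoffs a [model_cutoffs()].
#' @return logical: `TRUE` if the read (pair) is labeled as contamination.
#' @export
decide_label <- function(tally, cutoffs) {
  stopifnot(inherits(tally, "kmer_tally"), inherits(cutoffs, "model_cutoffs"))
  T_ <- tally$T
  if (T_ <= cutoffs$cutoff_tax2filter) return(FALSE)
  if (T_ == 0L) return(FALSE)
  if (!(T_ / (tally$O + T_) > cutoffs$cutoff_tax2keep)) return(FALSE)
  if (!(T_ / (tally$U + T_) > cutoffs$cutoff_unclassified)) return(FALSE)
  TRUE
}

#' Label read pairs from Kraken2 output with the cutoff model
#'
#' Resolves the target name in the taxonomy, expands it to its subtree,
#' tallies every record (mates pooled) and collects the normalized IDs of
#' the records passing all three conditions.
#'
#' @param records list of [kraken_record][parse_kraken_line] objects, or a
#'   path / character vector accepted by [read_kraken_output()].
#' @param tree a [taxonomy_tree][parse_taxdump].
#' @param tax2filter scientific name of the taxon to filter (subtree
#'   expanded), e.g. `"Homo sapiens"`.
#' @param cutoffs a [model_cutoffs()].
#' @param sample sample name recorded in the returned label set.
#' @return a [label_set()] with `tool = "kraken_model"`.
#' @export
label_kraken <- function(records, tree, tax2filter,
                         cutoffs = model_cutoffs(), sample = "sample") {
  if (!is.list(records) || (length(records) > 0L && !inherits(records[[1]], "kraken_record")))
    records <- read_kraken_output(records)
  target <- subtree(tree, resolve_name(tree, tax2filter))
  hit <- vapply(records, function(r) decide_label(kmer_tally(r, target), cutoffs),
                logical(1))
  ids <- vapply(records, `[[`, character(1), "read_id")
  label_set(normalize_id(ids[hit]), sample = sample, tool = "kraken_model")
}
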