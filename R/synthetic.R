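#' Synthetic communities for end-to-end testing
#'
#' Generates fully self-contained fixtures: a small taxonomy containing a
#' host species and several microbes, random genomes with optional shared
#' segments (to create genuinely ambiguous k-mers), error-bearing
#' paired-end reads with a truth manifest, and per-read classifier output
#' in the Kraken2 5-column format via a miniature LCA emulator. All
#' outputs are pure functions of (spec, params, seed).
#'
#' @name synthetic
NULL

#' Specify a synthetic community
#'
#' @param taxa data.frame with columns `tax_id`, `name`, `parent`, `rank`
#'   describing the taxonomy (root is its own parent).
#' @param host tax_id of the host (contaminant) species.
#' @param genome_length named numeric vector: tax_id (as character) ->
#'   genome length in bases. Only taxa listed here get genomes and reads.
#' @param abundances named numeric vector: tax_id -> read-pair
#'   proportion; must sum to 1 and cover exactly the genome taxa.
#' @param shared_segments optional data.frame with columns `taxon_a`,
#'   `taxon_b`, `length`: a segment of that length is copied verbatim from
#'   a's genome into b's, so the two share `length - k + 1` k-mers.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(taxa, host, genome_length, abundances,
                           shared_segments = NULL) {
  stopifnot(is.data.frame(taxa),
            all(c("tax_id", "name", "parent", "rank") %in% names(taxa)))
  if (!(host %in% taxa$tax_id))
    stop_hf("host taxon %s not in taxa table", host,
            class = "hostfilter_spec_error")
  if (!(as.character(host) %in% names(genome_length)))
    stop_hf("host taxon has no genome length", class = "hostfilter_spec_error")
  if (!setequal(names(genome_length), names(abundances)))
    stop_hf("abundances must cover exactly the genome taxa",
            class = "hostfilter_spec_error")
  if (abs(sum(abundances) - 1) > 1e-8)
    stop_hf("abundances must sum to 1 (got %g)", sum(abundances),
            class = "hostfilter_spec_error")
  if (!is.null(shared_segments)) {
    stopifnot(all(c("taxon_a", "taxon_b", "length") %in% names(shared_segments)))
    for (i in seq_len(nrow(shared_segments))) {
      la <- genome_length[[as.character(shared_segments$taxon_a[i])]]
      lb <- genome_length[[as.character(shared_segments$taxon_b[i])]]
      if (shared_segments$length[i] > min(la, lb))
        stop_hf("shared segment %d longer than a participating genome", i,
                class = "hostfilter_spec_error")
    }
  }
  structure(list(taxa = taxa, host = as.integer(host),
                 genome_length = genome_length, abundances = abundances,
                 shared_segments = shared_segments),
            class = "community_spec")
}

#' Default synthetic community
#'
#' One host species (Homo sapiens, reached through its genus so subtree
#' expansion is exercised) and three microbes under a small
#' cellular-organisms clade. Genomes 3--5 kb; host abundance 0.3,
#' emulating a heavily host-contaminated (stool-like) metagenome.
#'
#' @param shared_segments passed through to [community_spec()].
#' @return a [community_spec()].
#' @export
default_community_spec <- function(shared_segments = NULL) {
  taxa <- data.frame(
    tax_id = c(1L, 131567L, 9605L, 9606L, 2L, 562L, 1280L, 4932L),
    name = c("root", "cellular organisms", "Homo", "Homo sapiens",
             "Bacteria", "Escherichia coli", "Staphylococcus aureus",
             "Saccharomyces cerevisiae"),
    parent = c(1L, 1L, 131567L, 9605L, 131567L, 2L, 2L, 131567L),
    rank = c("no rank", "no rank", "genus", "species", "superkingdom",
             "species", "species", "species"),
    stringsAsFactors = FALSE)
  community_spec(
    taxa = taxa, host = 9606L,
    genome_length = c("9606" = 5000, "562" = 4000, "1280" = 3500,
                      "4932" = 3000),
    abundances = c("9606" = 0.3, "562" = 0.3, "1280" = 0.2, "4932" = 0.2),
    shared_segments = shared_segments)
}

#' Read-simulation parameters
#'
#' @param n_pairs number of read pairs.
#' @param read_length read length in bases (default 100).
#' @param insert_mean,insert_sd fragment (insert) size distribution
#'   (default 250 +/- 30 bases; draws are clamped to
#'   \[read_length, genome length\]).
#' @param error_rate per-base substitution probability (default 0.002,
#'   a typical short-read error rate; indels are not modelled).
#' @param seed RNG seed; identical seeds give identical output.
#' @return object of class `read_sim_params`.
#' @export
read_sim_params <- function(n_pairs, read_length = 100L, insert_mean = 250,
                            insert_sd = 30, error_rate = 0.002, seed = 1L) {
  stopifnot(n_pairs >= 0, read_length >= 1, read_length <= insert_mean,
            error_rate >= 0, error_rate < 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic community on disk
#'
#' Writes `nodes.dmp` / `names.dmp`, one FASTA per genome taxon plus a
#' combined `community.fasta` and host-only `host.fasta`, and a
#' provenance manifest. Shared segments are copied verbatim between the
#' two participating genomes after random generation.
#'
#' @param spec a [community_spec()].
#' @param seed RNG seed.
#' @param dir output directory (created).
#' @return list with `tree` (parsed back [taxonomy_tree][parse_taxdump]),
#'   `genomes` (named character vector, tax_id -> sequence), and `paths`.
#' @export
generate_community <- function(spec, seed = 1L, dir = tempfile("community")) {
  stopifnot(inherits(spec, "community_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  gl <- spec$genome_length
  genomes <- vapply(gl, function(l) random_genome(as.integer(l)), character(1))
  names(genomes) <- names(gl)

  ss <- spec$shared_segments
  if (!is.null(ss)) {
    for (i in seq_len(nrow(ss))) {
      a <- as.character(ss$taxon_a[i]); b <- as.character(ss$taxon_b[i])
      L <- as.integer(ss$length[i])
      pa <- sample.int(nchar(genomes[[a]]) - L + 1L, 1L)
      seg <- substr(genomes[[a]], pa, pa + L - 1L)
      pb <- sample.int(nchar(genomes[[b]]) - L + 1L, 1L)
      substr(genomes[[b]], pb, pb + L - 1L) <- seg
      # force the bases flanking the copy to differ from the donor's
      # flanks, so the shared run is exactly the requested length and the
      # segment contributes exactly L - k + 1 shared k-mers
      shift_base <- function(x) c(A = "C", C = "G", G = "T", T = "A")[[x]]
      if (pa > 1L && pb > 1L)
        substr(genomes[[b]], pb - 1L, pb - 1L) <-
          shift_base(substr(genomes[[a]], pa - 1L, pa - 1L))
      if (pa + L <= nchar(genomes[[a]]) && pb + L <= nchar(genomes[[b]]))
        substr(genomes[[b]], pb + L, pb + L) <-
          shift_base(substr(genomes[[a]], pa + L, pa + L))
    }
  }

  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  tx <- spec$taxa
  tree0 <- structure(list(ids = as.integer(tx$tax_id),
                          parent = as.integer(tx$parent),
                          rank = tx$rank, name = tx$name,
                          root = as.integer(tx$tax_id[tx$tax_id == tx$parent]),
                          children = NULL),
                     class = "taxonomy_tree")
  write_taxdump(tree0, nodes_path, names_path)
  tree <- parse_taxdump(nodes_path, names_path)

  fasta_paths <- character(0)
  for (tid in names(genomes)) {
    p <- file.path(dir, sprintf("genome_%s.fasta", tid))
    nm <- tx$name[match(as.integer(tid), tx$tax_id)]
    writeLines(c(sprintf(">%s %s", tid, nm), genomes[[tid]]), p)
    fasta_paths[tid] <- p
  }
  combined <- file.path(dir, "community.fasta")
  writeLines(unlist(lapply(names(genomes), function(tid)
    c(sprintf(">%s", tid), genomes[[tid]]))), combined)
  host_fa <- file.path(dir, "host.fasta")
  writeLines(c(sprintf(">%d host", spec$host),
               genomes[[as.character(spec$host)]]), host_fa)

  manifest <- file.path(dir, "provenance.tsv")
  utils::write.table(
    data.frame(tax_id = names(genomes),
               name = tx$name[match(as.integer(names(genomes)), tx$tax_id)],
               genome_length = nchar(genomes),
               fasta = basename(fasta_paths),
               is_host = as.integer(names(genomes)) == spec$host,
               seed = seed),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)

  list(tree = tree, genomes = genomes,
       paths = list(dir = dir, nodes = nodes_path, names = names_path,
                    fasta = fasta_paths, combined = combined,
                    host = host_fa, manifest = manifest))
}

#' Simulate error-bearing paired-end reads with a truth manifest
#'
#' Pairs are drawn from the genomes according to the community
#' abundances; the fragment strand is random, R1 is the fragment's 5' end
#' and R2 the reverse complement of its 3' end. Substitution errors are
#' applied i.i.d. per base. The manifest flags every pair whose source is
#' the host taxon as contaminant.
#'
#' @param genomes named character vector (tax_id -> sequence), e.g. from
#'   [generate_community()].
#' @param spec the [community_spec()].
#' @param params a [read_sim_params()].
#' @param dir output directory.
#' @return list with `r1`, `r2`, `manifest` (paths) and `truth`
#'   (data.frame `id`, `source_taxon`, `is_contaminant`).
#' @export
simulate_pairs <- function(genomes, spec, params, dir = tempfile("reads")) {
  stopifnot(inherits(spec, "community_spec"), inherits(params, "read_sim_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)
  n <- params$n_pairs
  L <- params$read_length
  if (any(nchar(genomes) < params$insert_mean))
    stop_hf("genome shorter than the mean insert size",
            class = "hostfilter_spec_error")

  src <- if (n > 0L)
    sample(names(spec$abundances), n, replace = TRUE, prob = spec$abundances)
  else character(0)

  r1 <- r2 <- character(n)
  for (i in seq_len(n)) {
    g <- genomes[[src[i]]]
    glen <- nchar(g)
    insert <- round(stats::rnorm(1, params$insert_mean, params$insert_sd))
    insert <- max(L, min(insert, glen))
    start <- sample.int(glen - insert + 1L, 1L)
    frag <- substr(g, start, start + insert - 1L)
    if (sample(c(TRUE, FALSE), 1L)) frag <- reverse_complement(frag)
    r1[i] <- add_substitutions(substr(frag, 1L, L), params$error_rate)
    r2[i] <- add_substitutions(
      reverse_complement(substr(frag, insert - L + 1L, insert)),
      params$error_rate)
  }
  ids <- if (n > 0L) sprintf("sim%d", seq_len(n)) else character(0)

  qual <- strrep("I", L)
  r1_path <- file.path(dir, "reads_R1.fastq")
  r2_path <- file.path(dir, "reads_R2.fastq")
  write_fastq_lines(as.vector(rbind(paste0("@", ids), r1, "+", qual)),
                    r1_path, gz = FALSE)
  write_fastq_lines(as.vector(rbind(paste0("@", ids), r2, "+", qual)),
                    r2_path, gz = FALSE)

  truth <- data.frame(id = ids, source_taxon = as.integer(src),
                      is_contaminant = as.integer(src) == spec$host,
                      stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(r1 = r1_path, r2 = r2_path, manifest = manifest_path, truth = truth)
}

add_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Emulate Kraken2 per-read output for simulated reads
#'
#' Builds a map from every canonical k-mer of the community genomes to
#' the LCA of all taxa containing it (mirroring Kraken2's strand
#' handling), then emits one 5-column line per pair: per-mate
#' run-length-encoded `taxid:count` tokens in read order, `0` for k-mers
#' absent from all genomes, `A` for windows spanning non-ACGT bases, and
#' mates joined by `|:|`. The consensus column carries the
#' count-plurality taxon; the cutoff model never reads it.
#'
#' @param genomes named character vector (tax_id -> sequence).
#' @param tree the community [taxonomy_tree][parse_taxdump].
#' @param r1,r2 FASTQ paths from [simulate_pairs()] (`r2` may be `NULL`
#'   for single-end emulation).
#' @param k k-mer length (default 35, Kraken2's classification k-mer
#'   size).
#' @param path optional output file; when given, lines are written there.
#' @return character vector of Kraken2-format lines (invisibly when
#'   `path` is given).
#' @export
emulate_kraken_output <- function(genomes, tree, r1, r2 = NULL, k = 35L,
                                  path = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  k <- as.integer(k)
  kmap <- new.env(hash = TRUE, parent = emptyenv())
  for (tid in names(genomes)) {
    tidi <- as.integer(tid)
    for (km in canonical_kmer(valid_kmers(toupper(genomes[[tid]]), k))) {
      prev <- kmap[[km]]
      kmap[[km]] <- if (is.null(prev)) tidi else lca(tree, c(prev, tidi))
    }
  }

  f1 <- read_fastq_records(r1)
  f2 <- if (!is.null(r2)) read_fastq_records(r2) else NULL
  if (!is.null(f2) && f2$n != f1$n)
    stop_hf("mate files differ in record count", class = "hostfilter_pairing_error")

  assign_mate <- function(seq) {
    seq <- toupper(seq)
    w <- seq_windows(seq, k)
    if (length(w) == 0L) return(character(0))
    ok <- acgt_window_mask(seq, k)
    out <- rep("A", length(w))
    if (any(ok)) {
      canon <- canonical_kmer_keepdup(w[ok])
      out[ok] <- vapply(canon, function(km) {
        v <- kmap[[km]]
        if (is.null(v)) "0" else as.character(v)
      }, character(1))
    }
    out
  }
  encode <- function(assignments) {
    if (length(assignments) == 0L) return("")
    r <- rle(assignments)
    paste(paste0(r$values, ":", r$lengths), collapse = " ")
  }

  lines <- character(f1$n)
  for (i in seq_len(f1$n)) {
    a1 <- assign_mate(f1$seq[i])
    a2 <- if (!is.null(f2)) assign_mate(f2$seq[i]) else NULL
    all_a <- c(a1, a2)
    classified <- any(!(all_a %in% c("0", "A")))
    counts <- table(all_a[!(all_a %in% c("0", "A"))])
    consensus <- if (classified) names(counts)[which.max(counts)] else "0"
    lens <- if (!is.null(f2)) sprintf("%d|%d", nchar(f1$seq[i]), nchar(f2$seq[i]))
            else sprintf("%d", nchar(f1$seq[i]))
    lca_field <- if (!is.null(f2)) paste(encode(a1), "|:|", encode(a2))
                 else encode(a1)
    lines[i] <- sprintf("%s\t%s\t%s\t%s\t%s",
                        if (classified) "C" else "U",
                        normalize_id_allow_empty(f1$id[i]),
                        consensus, lens, lca_field)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Canonical form preserving positions/duplicates (unlike canonical_kmer,
# which uniquifies for set construction).
canonical_kmer_keepdup <- function(kmers) {
  rc <- reverse_complement(kmers)
  swap <- rc < kmers
  kmers[swap] <- rc[swap]
  kmers
}
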