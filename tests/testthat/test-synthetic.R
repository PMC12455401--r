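kmer_set <- function(seq, k) canonical_kmer(substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq)))

test_that("generate_community writes disjoint genomes and a readable taxonomy", {
  spec <- default_community_spec()
  comm <- generate_community(spec, seed = 101, dir = tempfile())
  expect_length(comm$genomes, 4L)
  expect_equal(unname(nchar(comm$genomes)),
               unname(as.integer(spec$genome_length[names(comm$genomes)])))

  # taxonomy round-trips through the taxdump writer/parser
  expect_s3_class(comm$tree, "taxonomy_tree")
  expect_equal(resolve_name(comm$tree, "Homo sapiens"), 9606L)
  expect_setequal(subtree(comm$tree, 9605L), c(9605L, 9606L))

  # brute-force 27-mer disjointness across all genome pairs
  sets <- lapply(comm$genomes, kmer_set, k = 27)
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(sets[[i]], sets[[j]]), 0L)
})

test_that("a shared segment of length k+m-1 creates exactly m shared k-mers", {
  k <- 27L
  m <- 10L
  spec <- default_community_spec(
    shared_segments = data.frame(taxon_a = 9606, taxon_b = 562,
                                 length = k + m - 1))
  comm <- generate_community(spec, seed = 102, dir = tempfile())
  shared <- intersect(kmer_set(comm$genomes[["9606"]], k),
                      kmer_set(comm$genomes[["562"]], k))
  expect_length(shared, m)
})

test_that("community and read generation are deterministic in the seed", {
  spec <- default_community_spec()
  c1 <- generate_community(spec, seed = 5, dir = tempfile())
  c2 <- generate_community(spec, seed = 5, dir = tempfile())
  expect_identical(c1$genomes, c2$genomes)
  c3 <- generate_community(spec, seed = 6, dir = tempfile())
  expect_false(identical(c1$genomes, c3$genomes))

  p <- read_sim_params(50, seed = 9)
  r1 <- simulate_pairs(c1$genomes, spec, p, dir = tempfile())
  r2 <- simulate_pairs(c1$genomes, spec, p, dir = tempfile())
  expect_identical(readLines(r1$r1), readLines(r2$r1))
  expect_identical(readLines(r1$r2), readLines(r2$r2))
  expect_identical(r1$truth, r2$truth)
})

test_that("simulated reads honor the community parameters: lengths, manifest, zero-error substrings", {
  spec <- default_community_spec()
  comm <- generate_community(spec, seed = 103, dir = tempfile())

  empty <- simulate_pairs(comm$genomes, spec,
                          read_sim_params(0, seed = 1), dir = tempfile())
  expect_equal(nrow(empty$truth), 0L)

  p <- read_sim_params(80, error_rate = 0, seed = 11)
  sim <- simulate_pairs(comm$genomes, spec, p, dir = tempfile())
  expect_equal(nrow(sim$truth), 80L)
  expect_setequal(names(sim$truth), c("id", "source_taxon", "is_contaminant"))
  expect_equal(sim$truth$is_contaminant, sim$truth$source_taxon == 9606L)

  # error rate 0: every read is an exact substring of its genome (either strand)
  f1 <- readLines(sim$r1)
  seqs1 <- f1[seq(2, length(f1), 4)]
  f2 <- readLines(sim$r2)
  seqs2 <- f2[seq(2, length(f2), 4)]
  for (i in seq_len(20)) {
    g <- comm$genomes[[as.character(sim$truth$source_taxon[i])]]
    both <- paste(g, reverse_complement(g))
    expect_true(grepl(seqs1[i], both, fixed = TRUE) ||
                  grepl(reverse_complement(seqs1[i]), both, fixed = TRUE))
    expect_true(grepl(seqs2[i], both, fixed = TRUE) ||
                  grepl(reverse_complement(seqs2[i]), both, fixed = TRUE))
  }

  # a perfect filter on the manifest has recall 1 by definition
  truth_ids <- sim$truth$id[sim$truth$is_contaminant]
  expect_equal(recall(confusion_counts(truth_ids, truth_ids, sim$truth$id)), 1)
})

test_that("kraken emulation assigns host k-mers, LCA for shared segments, 0 for junk", {
  k <- 31L
  spec <- default_community_spec(
    shared_segments = data.frame(taxon_a = 9606, taxon_b = 562, length = 200))
  comm <- generate_community(spec, seed = 104, dir = tempfile())
  g <- comm$genomes

  # reads drawn straight from known regions
  host_read <- substr(g[["9606"]], 3001, 3100)   # outside any shared copy?
  junk <- random_dna(100)
  r1 <- write_test_fastq(c("h1", "j1"), c(host_read, junk),
                         tempfile(fileext = ".fastq"))
  lines <- emulate_kraken_output(g, comm$tree, r1, NULL, k = k)
  recs <- lapply(lines, parse_kraken_line)

  # host k-mers map to the host; any spanning a shared copy map to the
  # LCA of host and microbe ("cellular organisms" here)
  a_host <- recs[[1]]$kmer_runs[[1]]$assignment
  expect_true(all(a_host %in% c("9606", "131567")))
  junk_run <- recs[[2]]$kmer_runs[[1]]
  expect_equal(junk_run$assignment, "0")
  expect_equal(junk_run$count, 100L - k + 1L)
  expect_false(recs[[2]]$classified)

  # a read wholly inside the shared segment maps to the LCA of host and microbe
  seg <- intersect(kmer_set(g[["9606"]], 31), kmer_set(g[["562"]], 31))
  expect_gt(length(seg), 0)
  shared_read <- seg[1]
  r2 <- write_test_fastq("s1", shared_read, tempfile(fileext = ".fastq"))
  rec <- parse_kraken_line(emulate_kraken_output(g, comm$tree, r2, NULL, k = k))
  expect_equal(rec$kmer_runs[[1]]$assignment,
               as.character(lca(comm$tree, c(9606L, 562L))))

  # ambiguous bases produce A tokens
  r3 <- write_test_fastq("n1", paste0(substr(host_read, 1, 50), "N",
                                      substr(host_read, 52, 100)),
                         tempfile(fileext = ".fastq"))
  rec3 <- parse_kraken_line(emulate_kraken_output(g, comm$tree, r3, NULL, k = k))
  expect_true("A" %in% rec3$kmer_runs[[1]]$assignment)
})

test_that("invalid community specs are rejected", {
  spec <- default_community_spec()
  expect_error(community_spec(spec$taxa, host = 4242,
                              genome_length = spec$genome_length,
                              abundances = spec$abundances),
               class = "hostfilter_spec_error")
  bad_ab <- spec$abundances
  bad_ab[1] <- bad_ab[1] + 0.5
  expect_error(community_spec(spec$taxa, 9606, spec$genome_length, bad_ab),
               class = "hostfilter_spec_error")
  expect_error(default_community_spec(
    shared_segments = data.frame(taxon_a = 9606, taxon_b = 4932,
                                 length = 10000)),
    class = "hostfilter_spec_error")
  expect_error(simulate_pairs(c("9606" = "ACGT"), spec,
                              read_sim_params(1, read_length = 4,
                                              insert_mean = 10, seed = 1)),
               class = "hostfilter_spec_error")
})
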