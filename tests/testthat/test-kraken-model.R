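test_that("parse_kraken_line splits mates, ambiguity and unclassified tokens", {
  rec <- parse_kraken_line("C\tr1\t9606\t150|150\t9606:3 0:2 |:| A:1 9606:4")
  expect_s3_class(rec, "kraken_record")
  expect_true(rec$classified)
  expect_equal(rec$read_id, "r1")
  expect_equal(rec$lengths, c(150L, 150L))
  expect_length(rec$kmer_runs, 2L)
  expect_equal(rec$kmer_runs[[1]]$assignment, c("9606", "0"))
  expect_equal(rec$kmer_runs[[1]]$count, c(3L, 2L))
  expect_equal(rec$kmer_runs[[2]]$assignment, c("A", "9606"))
  expect_equal(rec$kmer_runs[[2]]$count, c(1L, 4L))

  un <- parse_kraken_line("U\tr2\t0\t150\t0:116")
  expect_false(un$classified)
  expect_length(un$kmer_runs, 1L)
  expect_equal(un$kmer_runs[[1]]$count, 116L)

  expect_error(parse_kraken_line("C\tr3"), class = "hostfilter_parse_error")
  expect_error(parse_kraken_line("C\tr\t1\t100\t9606;3"),
               class = "hostfilter_parse_error")
  expect_error(parse_kraken_line("X\tr\t1\t100\t0:1"),
               class = "hostfilter_parse_error")
})

test_that("kmer_tally pools mates, excludes ambiguous, splits T/O/U correctly", {
  rec <- parse_kraken_line("C\tr1\t9606\t150|150\t9606:3 0:2 |:| A:1 9606:4")
  t1 <- kmer_tally(rec, target = 9606L)
  expect_equal(c(t1$T, t1$O, t1$U), c(7L, 0L, 2L))

  un <- parse_kraken_line("U\tr2\t0\t150\t0:10")
  t2 <- kmer_tally(un, target = 9606L)
  expect_equal(c(t2$T, t2$O, t2$U), c(0L, 0L, 10L))

  # empty target: T = 0 always, everything classified counts as O
  t3 <- kmer_tally(rec, target = integer(0))
  expect_equal(t3$T, 0L)
  expect_equal(t3$O, 7L)

  # ancestors of the target count as O, not T
  anc <- parse_kraken_line("C\tr4\t1\t100\t1:5 9606:2 131567:3")
  t4 <- kmer_tally(anc, target = 9606L)
  expect_equal(c(t4$T, t4$O, t4$U), c(2L, 8L, 0L))
})

test_that("T+O+U conservation against an independent token-count oracle", {
  set.seed(11)
  tr <- fixture_tree()
  target <- subtree(tr, 10L)
  for (i in 1:50) {
    line <- random_kraken_line(sprintf("r%d", i))
    rec <- parse_kraken_line(line)
    tally <- kmer_tally(rec, target)
    oracle <- bf_tally_from_line(line, target)
    expect_equal(tally$T, unname(oracle["T"]))
    expect_equal(tally$O, unname(oracle["O"]))
    expect_equal(tally$U, unname(oracle["U"]))
    # conservation: T+O+U equals total non-ambiguous k-mer count
    total <- sum(unlist(lapply(rec$kmer_runs, function(r)
      r$count[r$assignment != "A"])))
    expect_equal(tally$T + tally$O + tally$U, total)
  }
})

make_tally <- function(T, O, U) {
  structure(list(T = T, O = O, U = U), class = "kmer_tally")
}

test_that("decide_label applies the three strict-inequality conditions", {
  c0 <- model_cutoffs(0, 0, 0)
  # one target k-mer suffices at cutoffs 0, whatever the competition
  expect_true(decide_label(make_tally(1L, 100L, 50L), c0))
  expect_false(decide_label(make_tally(0L, 5L, 5L), c0))
  expect_false(decide_label(make_tally(0L, 0L, 0L), c0))
  # ratio condition (ii): 3/8 = 0.375, not > 0.5
  expect_false(decide_label(make_tally(3L, 5L, 0L),
                            model_cutoffs(0, 0.5, 0)))
  # boundary of condition (iii): 3/12 = 0.25 is not > 0.25
  expect_false(decide_label(make_tally(3L, 0L, 9L),
                            model_cutoffs(0, 0, 0.25)))
  expect_true(decide_label(make_tally(4L, 0L, 9L),
                           model_cutoffs(0, 0, 0.25)))
  # condition (i) is a strict count threshold
  expect_false(decide_label(make_tally(2L, 0L, 0L), model_cutoffs(2, 0, 0)))
  expect_true(decide_label(make_tally(3L, 0L, 0L), model_cutoffs(2, 0, 0)))
})

test_that("cutoffs-0 decision is exactly equivalent to T >= 1", {
  set.seed(12)
  tr <- fixture_tree()
  target <- subtree(tr, 10L)
  c0 <- model_cutoffs(0, 0, 0)
  for (i in 1:200) {
    line <- random_kraken_line(sprintf("r%d", i))
    rec <- parse_kraken_line(line)
    expect_equal(decide_label(kmer_tally(rec, target), c0),
                 unname(bf_tally_from_line(line, target)["T"]) >= 1)
  }
})

test_that("decision is invariant under run permutation and mate swap", {
  set.seed(13)
  tr <- fixture_tree()
  target <- subtree(tr, 10L)
  cuts <- model_cutoffs(1, 0.3, 0.2)
  for (i in 1:30) {
    rec <- parse_kraken_line(random_kraken_line("r"))
    base <- decide_label(kmer_tally(rec, target), cuts)
    perm <- rec
    perm$kmer_runs <- lapply(rec$kmer_runs, function(r) r[sample(nrow(r)), ])
    swap <- rec
    swap$kmer_runs <- rev(rec$kmer_runs)
    expect_equal(decide_label(kmer_tally(perm, target), cuts), base)
    expect_equal(decide_label(kmer_tally(swap, target), cuts), base)
  }
})

test_that("raising any single cutoff never enlarges the label set", {
  set.seed(14)
  tr <- fixture_tree()
  lines <- vapply(1:120, function(i) random_kraken_line(sprintf("r%d", i)), "")
  labels_at <- function(cuts)
    label_kraken(lines, tr, "Left clade", cuts)$ids
  base_cuts <- list(tax2filter = c(0, 1, 2, 5, 10, 50),
                    tax2keep = c(0, 0.2, 0.5, 0.8, 1),
                    unclassified = c(0, 0.2, 0.5, 0.8, 1))
  prev <- labels_at(model_cutoffs(0, 0, 0))
  for (v in base_cuts$tax2filter[-1]) {
    cur <- labels_at(model_cutoffs(v, 0, 0))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- labels_at(model_cutoffs(0, 0, 0))
  for (v in base_cuts$tax2keep[-1]) {
    cur <- labels_at(model_cutoffs(0, v, 0))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- labels_at(model_cutoffs(0, 0, 0))
  for (v in base_cuts$unclassified[-1]) {
    cur <- labels_at(model_cutoffs(0, 0, v))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("label_kraken resolves the target, labels per pair, honors limits", {
  tr <- fixture_tree()
  lines <- c("C\ta\t111\t100|100\t111:5 0:2 |:| 111:3",
             "C\tb\t9606\t100|100\t9606:4 |:| 0:10",
             "U\tc\t0\t100|100\t0:8 |:| 0:8")
  ls <- label_kraken(lines, tr, "Left clade", model_cutoffs())
  expect_equal(ls$ids, "a")
  expect_equal(ls$tool, "kraken_model")

  expect_length(label_kraken(character(0), tr, "Left clade", model_cutoffs()), 0L)
  # a cutoff above every record's T empties the set
  expect_length(label_kraken(lines, tr, "Left clade",
                             model_cutoffs(100, 0, 0)), 0L)
  expect_error(label_kraken(lines, tr, "NoSuchTaxon", model_cutoffs()),
               class = "hostfilter_lookup_error")
})
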