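---
title: "Host-read decontamination: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-read decontamination: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostfilter)
```

## The problem

Shotgun metagenomes from human-associated (and many environmental)
samples carry human reads. Because a person — and their relatives — can
be re-identified from surprisingly little genetic data, human sequence
must be removed before datasets are shared, and the removal can never be
perfect: human variation is not fully covered by any reference, and some
sequence is genuinely shared between humans and other taxa. Every filter
therefore trades *thoroughness* (few surviving human pairs, measured as
recall) against *retention* (few microbial pairs wrongly discarded,
measured as precision), and different classifiers fail on different
reads, which is why combining two complementary classifiers and removing
the union of their calls is an effective strategy.

`hostfilter` implements both classifiers of such a two-pronged workflow,
the union merge and pair-level FASTQ filtering, the benchmark statistics,
and a synthetic data generator that makes all of it testable without any
reference downloads.

## The Kraken2 cutoff model

Kraken2 reports, per read, an ordered run-length encoding of the
taxonomic LCA assigned to each k-mer. Given a target taxon resolved by
scientific name and expanded to its full subtree, we tally per read pair

* **T** — k-mers assigned to any taxon in the target subtree,
* **O** — k-mers assigned to any other classified taxon,
* **U** — unclassified k-mers,

pooling both mates and discarding ambiguous-base (`A`) k-mers. The pair
is labeled as contamination iff

1. `T > cutoff_tax2filter` — an absolute k-mer count (default 0),
2. `T/(O+T) > cutoff_tax2keep` — a ratio in [0,1] (default 0),
3. `T/(U+T) > cutoff_unclassified` — a ratio in [0,1] (default 0).

Design choices worth stating explicitly, since the underlying workflow
leaves them open:

* **Strict inequalities.** At the all-zero defaults this reads "at least
  one target k-mer labels the pair", which is the behaviour we want from
  a maximally aggressive privacy filter; a tally exactly on a ratio
  cutoff is *not* labeled. With `T = 0` condition 1 already fails, so
  the ratios are never evaluated on an empty tally.
* **Ancestors count as O, not T.** A k-mer assigned to an ancestor of
  the target (e.g. "cellular organisms", or the root) is evidence
  *compatible* with the target but not *specific* to it; only the
  subtree is the target. This is visible in practice: reads from a
  region shared between host and a microbe get their k-mers assigned to
  the LCA above both and are consequently not labeled by this model.
* **Pairs are units.** Mate tallies are summed before the conditions
  are applied, and a pair is labeled or kept as a whole — evaluation
  and filtering also operate at pair granularity throughout.
* **Monotonicity.** Raising any single cutoff can only shrink the label
  set; the test suite sweeps each cutoff to verify this.

## The canonical k-mer membership classifier

The second classifier indexes the canonical k-mers of a reference FASTA
(canonical = lexicographic minimum of the k-mer and its reverse
complement, under A<C<G<T) and labels a pair when either mate shares at
least one k-mer with the index. The default `k = 27` follows the common
screening default. Windows containing non-ACGT characters are skipped on
both the reference and the read side, and sequence case is ignored.
Membership is deliberately exact — no mismatch neighbourhoods, no
middle-base masking — because the labeling contract is "shares a k-mer
with the reference", nothing more. A 100 b read has 74 27-mer windows,
so at realistic substitution rates nearly every true host read retains
at least one error-free window; the end-to-end tests confirm perfect
recovery at a 0.2% substitution rate.

## Merging, filtering, ID normalization

The final label set is the union over classifiers. Filtering then
removes labeled pairs from the FASTQ files. Two plumbing decisions
matter:

* **ID normalization.** Classifier-side and FASTQ-side identifiers drift
  (header comments, `@`, `/1`/`/2` mate suffixes), so all IDs pass
  through one rule: token before the first whitespace, leading `@` and
  one trailing mate suffix stripped. Labels that match no FASTQ record
  are counted and reported, never fatal.
* **Byte preservation.** Filtering operates on raw 4-line FASTQ records
  rather than re-encoded sequence objects, so kept plus removed records,
  re-interleaved in input order, byte-equal the input — an invariant the
  tests assert. Gzip is detected by magic bytes and mirrored on output.
  Wrapped (multi-line) FASTQ is rejected rather than silently
  re-wrapped.

## Evaluation statistics

With truth manifests, contaminant pairs are the positive class: FP and
TN are microbial, TP and FN host pairs; FP and TP were removed, TN and
FN survive. Recall `TP/(TP+FN)` and precision `TP/(TP+FP)` are reported
at 5 decimal places (full precision is kept internally). The universe of
pairs is taken from the manifest, not the FASTQ, so evaluation is
independent of filtering dialects. Composition skew between read
categories among retained versus removed reads is tested with a 2×2
Pearson χ² (df = 1) *without* continuity correction: at the intended
scale (≥10⁴ pairs per cell) the Yates correction is negligible;
small-table users should be aware it is off. Cross-method set algebra —
FN intersections over every non-empty method subset, FP unions with
per-method increments — quantifies what chaining filters would buy:
intersecting FN shows the contaminants *every* method misses, uniting FP
the retention price of removing the union.

## The synthetic data generator

The generator emulates the structure of a decontamination benchmark: a
small taxonomy (host species reached through its genus, so subtree
expansion is exercised, plus three microbes), random genomes, paired-end
reads with substitution errors and a truth manifest, and per-read
classifier output in the Kraken2 5-column format produced by a miniature
canonical-k-mer → LCA emulator.

Defaults, chosen once as a realistic small-scale analogue: 4 genomes of
3–5 kb; host abundance 0.3 (a heavily contaminated, stool-like sample);
reads 100 b, inserts 250 ± 30 b, substitution rate 0.002; emulated
classifier k-mers of 35 b and membership screening at 27 b. Problem
sizes in the tests and the acceptance script (200–1000 pairs, genomes of
a few kb) were chosen so the whole suite runs comfortably on a laptop
while still leaving k-mer collisions between random genomes effectively
impossible (4⁻²⁷ per pair of windows).

Controllable k-mer sharing: a `shared_segments` entry copies a segment
verbatim between two genomes, and the generator forces the bases
flanking the copy to differ so a length-`L` segment shares exactly
`L−k+1` k-mers — making "genuinely ambiguous" k-mers a precise, testable
quantity. On such a community the two classifiers split exactly as
intended: microbial reads overlapping the segment are false positives of
the membership classifier but are kept by the cutoff model (their
k-mers map to the LCA above the host), while host reads inside the
segment are missed by the cutoff model but caught by the membership
classifier — the union is strictly more thorough.

What the generator does *not* emulate: quality-dependent or
platform-specific error profiles (substitutions only, no indels), real
genome repeat structure, real taxonomies' size, or real databases'
incompleteness. Passing end-to-end tests therefore demonstrate the
correctness of the pipeline's logic, not the field performance of any
database; the benchmark arithmetic the acceptance script reproduces
comes from published confusion counts, used as printed inputs.

## Numerical and degenerate-input conventions

* Recall/precision are errors, not NaN, when their denominators are
  empty (`TP+FN = 0`, `TP+FP = 0`), as is a χ² table with a zero row or
  column.
* Reads shorter than k never hit the membership index; records with no
  k-mer runs tally to `T = O = U = 0` and are never labeled.
* Name resolution prefers an exact case-sensitive match, then falls back
  case-insensitively; ambiguity is an error listing the candidates, and
  only scientific names (not synonyms or common names) are indexed.
* The taxonomy root is detected as the unique self-parent node; missing
  parents and cycles are structural errors naming the offending taxon.
* All synthetic outputs are pure functions of (spec, params, seed); the
  determinism tests require byte-identical artifacts under a fixed seed.

## Known limitations

* The cutoff model consumes existing Kraken2 per-read output; it does
  not reimplement Kraken2's classifier or databases.
* The membership classifier stores k-mers as character strings; ample
  for reference fixtures up to megabases, but a 2-bit packed index would
  be the next step for full host genomes.
* Single-end data is supported throughout, but interleaved FASTQ and
  wrapped FASTQ dialects are not.
* Whether a real pipeline would label a pair when only one mate
  satisfies the cutoffs separately is unspecified upstream; we pool mate
  tallies before the conditions, which is the natural reading of
  pair-level labeling.
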