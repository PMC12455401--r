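Package: hostfilter
Title: Host-Read Decontamination of Metagenomic Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and removes host (typically human) read pairs from
    shotgun metagenomic FASTQ data. Implements a three-condition k-mer
    cutoff model over Kraken2 per-read classifications, an exact canonical
    k-mer membership classifier built from a reference FASTA, union merging
    of label sets with paired-FASTQ filtering, and benchmark evaluation
    statistics (recall, precision, 2x2 chi-squared composition tests, and
    cross-method false-negative/false-positive set algebra). A synthetic
    community generator (taxonomy, genomes with controllable k-mer sharing,
    error-bearing paired reads with truth manifests, and emulated Kraken2
    per-read output) makes the whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
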