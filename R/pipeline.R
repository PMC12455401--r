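#' Run the full decontamination pipeline on one sample
#'
#' Wires the classifiers together in the standard order: label with the
#' Kraken2 cutoff model and/or the k-mer membership classifier, merge the
#' label sets (union), optionally filter the FASTQ files and emit the
#' removed reads, summarize per-tool labeling effort, and — when a truth
#' manifest is available — evaluate recall and precision.
#'
#' @param config a list (see [run_config()]).
#' @return list with the label sets, the summary data.frame, filter
#'   counts (when filtering ran) and a [method_result()] (when a truth
#'   manifest was given); artifacts are written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  outdir <- file.path(config$outdir, config$sample)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  n_pairs <- read_fastq_records(config$r1)$n
  sets <- list()

  if (isTRUE(config$classification_kraken2)) {
    tree <- parse_taxdump(config$nodes, config$names)
    sets$kraken <- label_kraken(config$kraken_output, tree,
                                config$tax2filter, config$cutoffs,
                                sample = config$sample)
    write_label_list(sets$kraken, file.path(outdir, "labels_kraken_model.txt"))
  }
  if (isTRUE(config$classification_bbduk)) {
    index <- build_kmer_index(config$fasta_bbduk, k = config$bbduk_kmers)
    sets$kmer <- label_fastq(index, config$r1, config$r2,
                             sample = config$sample)
    write_label_list(sets$kmer, file.path(outdir, "labels_kmer_classifier.txt"))
  }
  merged <- merge_labels(unname(sets))
  write_label_list(merged, file.path(outdir, "labels_merged.txt"))

  totals <- stats::setNames(n_pairs, config$sample)
  summary <- summarize_labels(c(unname(sets), list(merged)), totals)
  write_summary_tsv(summary, file.path(outdir, "summary.tsv"))

  filter_res <- NULL
  if (isTRUE(config$enable_filter))
    filter_res <- filter_fastq(merged, config$r1, config$r2, out_dir = outdir,
                               emit_removed = isTRUE(config$output_removed_reads))

  eval_res <- NULL
  if (!is.null(config$truth_manifest)) {
    eval_res <- evaluate_removal(merged$ids, config$truth_manifest,
                                 name = "merged")
    write_evaluation_tsv(eval_res, file.path(outdir, "evaluation.tsv"))
  }

  write_run_log(config, file.path(outdir, "run.log"))
  invisible(list(labels = sets, merged = merged, summary = summary,
                 filter = filter_res, evaluation = eval_res,
                 outdir = outdir))
}

#' Assemble a pipeline run configuration
#'
#' @param sample sample name.
#' @param r1,r2 FASTQ(.gz) paths (`r2` optional).
#' @param kraken_output Kraken2 standard per-read output for the sample
#'   (needed when `classification_kraken2`).
#' @param nodes,names taxdump files (needed when `classification_kraken2`).
#' @param tax2filter target taxon name whose subtree is labeled
#'   (default `"Homo sapiens"`).
#' @param cutoffs a [model_cutoffs()].
#' @param fasta_bbduk reference FASTA for the k-mer classifier (needed
#'   when `classification_bbduk`).
#' @param bbduk_kmers k-mer size of the membership classifier (default 27).
#' @param classification_kraken2,classification_bbduk which classifiers to
#'   run; at least one must be enabled.
#' @param enable_filter actually remove labeled pairs from the FASTQs.
#' @param output_removed_reads also write the removed pairs.
#' @param truth_manifest optional truth TSV for evaluation.
#' @param outdir output directory (one subdirectory per sample).
#' @param seed seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters for simulation).
#' @return a validated config list.
#' @export
run_config <- function(sample, r1, r2 = NULL, kraken_output = NULL,
                       nodes = NULL, names = NULL,
                       tax2filter = "Homo sapiens",
                       cutoffs = model_cutoffs(),
                       fasta_bbduk = NULL, bbduk_kmers = 27L,
                       classification_kraken2 = TRUE,
                       classification_bbduk = FALSE,
                       enable_filter = FALSE,
                       output_removed_reads = FALSE,
                       truth_manifest = NULL,
                       outdir = ".", seed = 1L) {
  validate_run_config(as.list(environment()))
}

validate_run_config <- function(config) {
  if (!isTRUE(config$classification_kraken2) &&
      !isTRUE(config$classification_bbduk))
    stop_hf("at least one classifier must be enabled",
            class = "hostfilter_usage_error")
  if (isTRUE(config$classification_kraken2) &&
      (is.null(config$kraken_output) || is.null(config$nodes) ||
       is.null(config$names)))
    stop_hf("kraken model needs kraken_output, nodes and names",
            class = "hostfilter_usage_error")
  if (isTRUE(config$classification_bbduk) && is.null(config$fasta_bbduk))
    stop_hf("k-mer classifier needs fasta_bbduk",
            class = "hostfilter_usage_error")
  if (is.null(config$cutoffs)) config$cutoffs <- model_cutoffs()
  if (!inherits(config$cutoffs, "model_cutoffs"))
    stop_hf("cutoffs must be a model_cutoffs object",
            class = "hostfilter_usage_error")
  config
}

write_run_log <- function(config, path) {
  hashable <- config[!vapply(config, is.null, logical(1))]
  hash_file <- tempfile()
  writeLines(utils::capture.output(utils::str(hashable)), hash_file)
  lines <- c(
    sprintf("hostfilter version: %s",
            as.character(utils::packageVersion("hostfilter"))),
    sprintf("R version: %s", R.version.string),
    sprintf("config hash: %s", unname(tools::md5sum(hash_file))),
    sprintf("seed: %s", config$seed %||% NA),
    sprintf("sample: %s", config$sample))
  unlink(hash_file)
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an evaluation result as TSV
#'
#' One row with confusion counts and recall/precision at 5 decimals.
#'
#' @param res a [method_result()].
#' @param path output path.
#' @export
write_evaluation_tsv <- function(res, path) {
  stopifnot(inherits(res, "method_result"))
  df <- data.frame(method = res$name,
                   TP = res$confusion$TP, FP = res$confusion$FP,
                   FN = res$confusion$FN, TN = res$confusion$TN,
                   recall = sprintf("%.5f", res$recall),
                   precision = sprintf("%.5f", res$precision),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a key=value run-configuration file
#'
#' Plain `key = value` lines; `#` starts a comment. Logical values are
#' `true`/`false`; the three model cutoffs are collected into a
#' [model_cutoffs()] object.
#'
#' @param path config file path.
#' @return config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  cfg <- stats::setNames(as.list(vals), keys)
  for (k in c("classification_kraken2", "classification_bbduk",
              "enable_filter", "output_removed_reads"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- tolower(cfg[[k]]) %in% c("true", "1", "yes")
  for (k in c("bbduk_kmers", "seed"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  cfg$cutoffs <- model_cutoffs(
    as.numeric(cfg$cutoff_tax2filter %||% 0),
    as.numeric(cfg$cutoff_tax2keep %||% 0),
    as.numeric(cfg$cutoff_unclassified %||% 0))
  cfg$cutoff_tax2filter <- cfg$cutoff_tax2keep <- cfg$cutoff_unclassified <- NULL
  if (is.null(cfg$bbduk_kmers)) cfg$bbduk_kmers <- 27L
  if (is.null(cfg$tax2filter)) cfg$tax2filter <- "Homo sapiens"
  if (is.null(cfg$outdir)) cfg$outdir <- "."
  validate_run_config(cfg)
}
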