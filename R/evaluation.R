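#' Benchmark evaluation of decontamination results
#'
#' Ground truth is a manifest of read-pair IDs flagged as contaminant
#' (host) or clean (microbial). Under this convention FP and TN are
#' microbial pairs, TP and FN host pairs; FP and TP were removed, TN and
#' FN survive into the decontaminated data. Recall `TP/(TP+FN)` measures
#' how thoroughly contamination was removed; precision `TP/(TP+FP)` how
#' well clean reads were retained.
#'
#' @name evaluation
NULL

#' Confusion counts of a decontamination run
#'
#' @param removed character vector of removed read-pair IDs.
#' @param truth_contaminant character vector of IDs flagged as contaminant
#'   in the truth manifest.
#' @param universe character vector of all read-pair IDs (the truth
#'   manifest's ID column).
#' @return object of class `confusion_counts`: list with integer `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(removed, truth_contaminant, universe) {
  removed <- unique(as.character(removed))
  truth_contaminant <- unique(as.character(truth_contaminant))
  universe <- unique(as.character(universe))
  if (length(setdiff(truth_contaminant, universe)) > 0L)
    stop_hf("truth-contaminant IDs outside the universe",
            class = "hostfilter_usage_error")
  if (length(setdiff(removed, universe)) > 0L)
    stop_hf("removed IDs outside the universe",
            class = "hostfilter_usage_error")
  tp <- length(intersect(removed, truth_contaminant))
  structure(list(TP = tp,
                 FP = length(removed) - tp,
                 FN = length(truth_contaminant) - tp,
                 TN = length(universe) - length(union(removed, truth_contaminant))),
            class = "confusion_counts")
}

#' Build confusion counts directly from the four cell values
#'
#' Convenience for evaluating published confusion tables.
#'
#' @param TP,FP,TN,FN non-negative read-pair counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_from_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%s FP=%s FN=%s TN=%s\n",
              format(x$TP, big.mark = ","), format(x$FP, big.mark = ","),
              format(x$FN, big.mark = ","), format(x$TN, big.mark = ",")))
  invisible(x)
}

#' Recall of a decontamination run
#'
#' `TP / (TP + FN)`: the fraction of true contaminant pairs that were
#' removed — the headline measure of decontamination success.
#'
#' @param x a [confusion_counts()].
#' @param digits decimal places for reporting (default 5, matching the
#'   benchmark convention); `NULL` returns full double precision.
#' @return numeric proportion in \[0,1\].
#' @export
recall <- function(x, digits = 5L) {
  stopifnot(inherits(x, "confusion_counts"))
  if (x$TP + x$FN <= 0)
    stop_hf("recall undefined: no truth-contaminant pairs (TP+FN = 0)",
            class = "hostfilter_metric_error")
  r <- x$TP / (x$TP + x$FN)
  if (is.null(digits)) r else round(r, digits)
}

#' Precision of a decontamination run
#'
#' `TP / (TP + FP)`: the fraction of removed pairs that really were
#' contaminant — how well microbial reads were retained.
#'
#' @inheritParams recall
#' @return numeric proportion in \[0,1\].
#' @export
precision <- function(x, digits = 5L) {
  stopifnot(inherits(x, "confusion_counts"))
  if (x$TP + x$FP <= 0)
    stop_hf("precision undefined: nothing was removed (TP+FP = 0)",
            class = "hostfilter_metric_error")
  p <- x$TP / (x$TP + x$FP)
  if (is.null(digits)) p else round(p, digits)
}

#' 2x2 chi-squared test of independence
#'
#' Pearson chi-squared with one degree of freedom and no continuity
#' correction, used to test whether the composition of two read
#' categories (e.g. the two microbial sub-datasets) among removed (FP)
#' versus retained (TN) reads is independent of the outcome. At the
#' read-pair counts this test is meant for (>= 1e4 per cell) the Yates
#' correction is negligible; small-table users should be aware it is
#' deliberately off.
#'
#' @param a,b first row (e.g. category counts among FP).
#' @param c,d second row (e.g. category counts among TN).
#' @return list with `statistic` and `p_value`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  if (sum(m) <= 0 || any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_hf("degenerate 2x2 table: zero row/column total",
            class = "hostfilter_degenerate_table_error")
  res <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Per-method decontamination result
#'
#' Bundles one method's removed-ID set with its confusion against the
#' truth; FN IDs are the contaminants the method missed, FP IDs the clean
#' pairs it wrongly removed. These ID sets feed the cross-method set
#' algebra ([fn_intersections()], [fp_union()]).
#'
#' @param name method label.
#' @param removed character vector of removed read-pair IDs.
#' @param truth_contaminant,universe as in [confusion_counts()].
#' @return object of class `method_result`.
#' @export
method_result <- function(name, removed, truth_contaminant, universe) {
  removed <- unique(as.character(removed))
  truth_contaminant <- unique(as.character(truth_contaminant))
  cc <- confusion_counts(removed, truth_contaminant, universe)
  structure(list(name = name,
                 removed = removed,
                 fn_ids = setdiff(truth_contaminant, removed),
                 fp_ids = setdiff(removed, truth_contaminant),
                 confusion = cc,
                 recall = recall(cc),
                 precision = precision(cc)),
            class = "method_result")
}

#' Sizes of false-negative intersections across methods
#'
#' For every non-empty subset of methods, the number of contaminant pairs
#' that *all* methods in the subset missed — the quantity behind
#' upset-style plots asking whether chaining methods would recover reads a
#' single method misses.
#'
#' @param methods list of [method_result()] objects.
#' @return named integer vector, one entry per non-empty method subset
#'   (`2^k - 1` entries), names joined with `"+"`.
#' @export
fn_intersections <- function(methods) {
  stopifnot(is.list(methods), length(methods) >= 1L,
            all(vapply(methods, inherits, logical(1), "method_result")))
  nm <- vapply(methods, `[[`, character(1), "name")
  k <- length(methods)
  out <- integer(0)
  for (size in seq_len(k)) {
    for (comb in as.data.frame(utils::combn(k, size))) {
      inter <- Reduce(intersect, lapply(methods[comb], `[[`, "fn_ids"))
      out[paste(nm[comb], collapse = "+")] <- length(inter)
    }
  }
  out
}

#' Union of false positives across methods
#'
#' Chaining methods removes the union of their removed sets, so its FP
#' burden is the union of the per-method FP sets. Reports the union size
#' and, per method, the FP IDs it adds over a chosen base method.
#'
#' @param methods list of [method_result()] objects.
#' @param base index or name of the base method (default the first).
#' @return list with `union` (count), `base` (name), and `increment`
#'   (named integer vector: FP added by each method over the base).
#' @export
fp_union <- function(methods, base = 1L) {
  stopifnot(is.list(methods), length(methods) >= 1L,
            all(vapply(methods, inherits, logical(1), "method_result")))
  nm <- vapply(methods, `[[`, character(1), "name")
  if (is.character(base)) base <- match(base, nm)
  stopifnot(!is.na(base), base >= 1L, base <= length(methods))
  fp_sets <- lapply(methods, `[[`, "fp_ids")
  increment <- vapply(fp_sets, function(s) length(setdiff(s, fp_sets[[base]])),
                      integer(1))
  names(increment) <- nm
  list(union = length(unique(unlist(fp_sets, use.names = FALSE))),
       base = nm[base],
       increment = increment)
}

#' Read a truth manifest
#'
#' @param path TSV with header `id`, `source_taxon`, `is_contaminant`
#'   (written by [simulate_pairs()] or supplied externally).
#' @return data.frame with those columns (`is_contaminant` logical).
#' @export
read_truth_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "logical"),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("id", "source_taxon", "is_contaminant") %in% names(df)))
  df
}

#' Evaluate removed IDs against a truth manifest
#'
#' The universe of pairs is the manifest's ID column, so evaluation is
#' independent of FASTQ header dialects.
#'
#' @param removed character vector of removed IDs, or a path to an
#'   ID-per-line file.
#' @param manifest data.frame from [read_truth_manifest()], or a path.
#' @param name method label.
#' @return a [method_result()].
#' @export
evaluate_removal <- function(removed, manifest, name = "method") {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read_truth_manifest(manifest)
  if (length(removed) == 1L && file.exists(removed))
    removed <- read_label_list(removed)$ids
  if (inherits(removed, "label_set")) removed <- removed$ids
  method_result(name, removed,
                truth_contaminant = manifest$id[manifest$is_contaminant],
                universe = manifest$id)
}
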