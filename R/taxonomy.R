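#' Taxonomy trees in the NCBI taxdump dialect
#'
#' A `taxonomy_tree` is a parent-pointer tree over integer taxon IDs with
#' rank labels and scientific names, as read from `nodes.dmp` /
#' `names.dmp` style files. It supports name-to-ID resolution (the target
#' of decontamination is given as a taxonomic name such as
#' `"Homo sapiens"`) and subtree expansion: when the target is an internal
#' node, its whole subtree is flagged for removal.
#'
#' @name taxonomy_tree
NULL

#' Parse a taxdump-dialect taxonomy
#'
#' Accepts both the classic `" | "`-padded and bare `"|"` field delimiters;
#' fields beyond the rank in `nodes.dmp` are ignored. Only entries of name
#' class `"scientific name"` populate the name table (when `names.dmp`
#' carries a class column; two-field name lines are taken as scientific
#' names). The root is detected as the unique self-parent node, never
#' hard-coded to taxon 1.
#'
#' @param nodes_lines character vector of `nodes.dmp` lines, or a file path
#'   (single string naming an existing file).
#' @param names_lines character vector of `names.dmp` lines, or a file path.
#' @return an object of class `taxonomy_tree` with components `ids`
#'   (integer), `parent` (integer, parallel to `ids`), `rank` (character),
#'   `name` (character, NA where unnamed), `root` (integer), and
#'   `children` (list: taxon ID as character -> integer vector of child IDs).
#' @examples
#' tr <- parse_taxdump(c("1\t|\t1\t|\tno rank\t|"), character(0))
#' tr$root
#' @export
parse_taxdump <- function(nodes_lines, names_lines = character(0)) {
  nodes_lines <- read_lines_or_passthrough(nodes_lines)
  names_lines <- read_lines_or_passthrough(names_lines)

  nf <- split_dmp(nodes_lines)
  if (length(nf) == 0L)
    stop_hf("empty nodes stream", class = "hostfilter_structure_error")
  ids <- vapply(nf, function(f) as.integer(f[1]), integer(1))
  parent <- vapply(nf, function(f) as.integer(f[2]), integer(1))
  rank <- vapply(nf, function(f) if (length(f) >= 3L) f[3] else NA_character_,
                 character(1))
  if (anyNA(ids) || anyNA(parent))
    stop_hf("malformed nodes line: non-numeric taxon or parent ID",
            class = "hostfilter_structure_error")
  if (anyDuplicated(ids))
    stop_hf("duplicate taxon ID %d in nodes", ids[duplicated(ids)][1],
            class = "hostfilter_structure_error")

  missing_parent <- setdiff(parent, ids)
  if (length(missing_parent) > 0L)
    stop_hf("parent taxon %d referenced but not defined",
            missing_parent[1], class = "hostfilter_structure_error")

  root <- ids[ids == parent]
  if (length(root) != 1L)
    stop_hf("expected exactly one self-parent root node, found %d",
            length(root), class = "hostfilter_structure_error")

  # Cycle check: follow parents from every node; a walk longer than the
  # node count without reaching the root proves a cycle.
  pmap <- parent
  names(pmap) <- as.character(ids)
  for (id in ids) {
    cur <- id
    steps <- 0L
    while (cur != root) {
      cur <- pmap[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > length(ids))
        stop_hf("cycle detected involving taxon %d", id,
                class = "hostfilter_structure_error")
    }
  }

  name <- rep(NA_character_, length(ids))
  if (length(names_lines) > 0L) {
    fl <- split_dmp(names_lines)
    for (f in fl) {
      if (length(f) < 2L) next
      cls <- if (length(f) >= 4L) f[4] else "scientific name"
      if (!identical(cls, "scientific name")) next
      tid <- as.integer(f[1])
      idx <- match(tid, ids)
      if (!is.na(idx)) name[idx] <- f[2]
    }
  }

  # child index built once at parse: O(nodes)
  nonroot <- ids != parent
  children <- split(ids[nonroot], as.character(parent[nonroot]))
  children <- lapply(children, as.integer)

  structure(list(ids = ids, parent = parent, rank = rank, name = name,
                 root = root, children = children),
            class = "taxonomy_tree")
}

read_lines_or_passthrough <- function(x) {
  if (length(x) == 1L && !grepl("[\t|]", x) && file.exists(x))
    readLines(x)
  else
    x
}

# Split pipe-delimited dmp lines into trimmed fields; tolerates both
# " | "-padded and bare "|" delimiters and a trailing delimiter.
split_dmp <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(lines, "|", fixed = TRUE), function(f) {
    f <- trimws(f, whitespace = "[ \t]")
    if (length(f) > 0L && !nzchar(f[length(f)])) f <- f[-length(f)]
    f
  })
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d taxa, root=%d, %d named\n",
              length(x$ids), x$root, sum(!is.na(x$name))))
  invisible(x)
}

#' Resolve a taxonomic name to its taxon ID
#'
#' Exact (case-sensitive) match against scientific names first, then a
#' case-insensitive fallback. Ambiguity (a name borne by several taxa at
#' the matched level) is an error.
#'
#' @param tree a [taxonomy_tree][parse_taxdump].
#' @param name scientific name to look up, e.g. `"Homo sapiens"`.
#' @return integer taxon ID.
#' @export
resolve_name <- function(tree, name) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  hit <- which(!is.na(tree$name) & tree$name == name)
  if (length(hit) == 0L)
    hit <- which(!is.na(tree$name) & tolower(tree$name) == tolower(name))
  if (length(hit) == 0L) {
    known <- tree$name[!is.na(tree$name)]
    near <- utils::head(known[order(utils::adist(tolower(known), tolower(name)))], 3L)
    stop_hf("no taxon named '%s'; nearest names: %s", name,
            paste(near, collapse = ", "), class = "hostfilter_lookup_error")
  }
  if (length(hit) > 1L)
    stop_hf("name '%s' is ambiguous: taxa %s", name,
            paste(tree$ids[hit], collapse = ", "),
            class = "hostfilter_lookup_error")
  tree$ids[hit]
}

#' Expand a taxon to its full subtree
#'
#' Returns the taxon itself plus every descendant; ancestors are never
#' included. The decontamination target set is always a subtree: flagging
#' an internal node (e.g. a genus) flags all leaves below it.
#'
#' @param tree a [taxonomy_tree][parse_taxdump].
#' @param taxon integer taxon ID present in the tree.
#' @return integer vector of taxon IDs (sorted).
#' @export
subtree <- function(tree, taxon) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxon <- as.integer(taxon)
  if (!(taxon %in% tree$ids))
    stop_hf("taxon %d not in tree", taxon, class = "hostfilter_lookup_error")
  out <- integer(0)
  queue <- taxon
  while (length(queue) > 0L) {
    cur <- queue[1]
    queue <- queue[-1]
    out <- c(out, cur)
    kids <- tree$children[[as.character(cur)]]
    if (!is.null(kids)) queue <- c(queue, kids)
  }
  sort(out)
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a [taxonomy_tree][parse_taxdump].
#' @param taxa integer vector of taxon IDs.
#' @return integer taxon ID of the deepest node ancestral to all of `taxa`.
#' @export
lca <- function(tree, taxa) {
  stopifnot(inherits(tree, "taxonomy_tree"), length(taxa) >= 1L)
  paths <- lapply(as.integer(taxa), function(t) ancestor_path(tree, t))
  common <- Reduce(intersect, paths)
  if (length(common) == 0L)
    stop_hf("taxa share no ancestor (disconnected tree?)",
            class = "hostfilter_structure_error")
  # paths are root-last; the common node appearing earliest in the first
  # path is the deepest common ancestor
  common[which.min(match(common, paths[[1]]))]
}

# Path from taxon to root, taxon first.
ancestor_path <- function(tree, taxon) {
  if (!(taxon %in% tree$ids))
    stop_hf("taxon %d not in tree", taxon, class = "hostfilter_lookup_error")
  pmap <- tree$parent
  names(pmap) <- as.character(tree$ids)
  path <- taxon
  cur <- taxon
  while (cur != tree$root) {
    cur <- pmap[[as.character(cur)]]
    path <- c(path, cur)
  }
  path
}

#' Serialise a taxonomy to nodes.dmp / names.dmp
#'
#' Writer for fixtures; emits the classic `" | "`-padded, `"|"`-terminated
#' dialect that [parse_taxdump()] reads back identically.
#'
#' @param tree a [taxonomy_tree][parse_taxdump].
#' @param nodes_path,names_path output file paths.
#' @return invisibly, a list with the two paths.
#' @export
write_taxdump <- function(tree, nodes_path, names_path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", tree$ids, tree$parent,
                   ifelse(is.na(tree$rank), "no rank", tree$rank))
  writeLines(nodes, nodes_path)
  has <- !is.na(tree$name)
  names_out <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                       tree$ids[has], tree$name[has])
  writeLines(names_out, names_path)
  invisible(list(nodes = nodes_path, names = names_path))
}
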