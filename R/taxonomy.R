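#' Parse NCBI-style taxonomy dump files into a rooted taxonomy tree
#'
#' Reads `nodes.dmp` and `names.dmp` in the NCBI dump dialect (fields
#' separated by `\t|\t`, records terminated by `\t|`; plain `|` separators
#' with surrounding whitespace are accepted too) and builds a
#' `taxonomy_tree`: one node per taxid carrying its parent, rank and
#' scientific name.  By NCBI convention the root (taxid 1 in real dumps) is
#' its own parent; exactly one such node must exist.
#'
#' Only fields 1-3 of `nodes.dmp` (taxid, parent taxid, rank) and fields
#' 1, 2 and 4 of `names.dmp` (taxid, name, name class) are consulted.  The
#' scientific name of a taxon is taken from the `names.dmp` record whose
#' name class is `"scientific name"`; other classes (synonyms, common
#' names, ...) are ignored.  Merged or deleted taxids are not handled:
#' lookups of unknown taxids are errors throughout the package.
#'
#' @param nodes path to a `nodes.dmp`-dialect file, or a character vector of
#'   its lines.
#' @param names path to a `names.dmp`-dialect file, or a character vector of
#'   its lines.
#' @return An object of class `taxonomy_tree`: a list with element `nodes`,
#'   a data.frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `scientific_name`, and element `root`, the root taxid.
#' @examples
#' nodes <- c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tsuperkingdom\t|")
#' names <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
#'            "2\t|\tBacteria\t|\t\t|\tscientific name\t|")
#' tr <- parse_taxonomy(nodes, names)
#' lineage(tr, 2)
#' @seealso [lineage()], [lca()], [ancestor_at_rank()], [write_taxonomy()]
#' @export
parse_taxonomy <- function(nodes, names) {
  nrec <- read_dmp(nodes)
  if (length(nrec) == 0L) stop("nodes stream is empty")
  bad <- which(vapply(nrec, length, 1L) < 3L)
  if (length(bad)) {
    stop("nodes record ", bad[1L], " has fewer than 3 fields")
  }
  taxid <- vapply(nrec, function(f) as_taxid(f[1L], "taxid"), 1L)
  parent <- vapply(nrec, function(f) as_taxid(f[2L], "parent taxid"), 1L)
  rank <- vapply(nrec, function(f) f[3L], "")
  if (anyDuplicated(taxid)) {
    stop("duplicate taxid in nodes stream: ", taxid[duplicated(taxid)][1L])
  }

  mrec <- read_dmp(names)
  sci <- character(0)
  if (length(mrec)) {
    ntax <- vapply(mrec, function(f) as_taxid(f[1L], "taxid"), 1L)
    nname <- vapply(mrec, function(f) f[2L], "")
    nclass <- vapply(mrec, function(f) if (length(f) >= 4L) f[4L] else "", "")
    keep <- nclass == "scientific name"
    sci <- nname[keep]
    names(sci) <- as.character(ntax[keep])
  }
  sname <- unname(sci[as.character(taxid)])
  miss <- which(is.na(sname) | !nzchar(sname))
  if (length(miss)) {
    stop("no scientific name for taxid ", taxid[miss[1L]])
  }

  df <- data.frame(taxid = taxid, parent_taxid = parent, rank = rank,
                   scientific_name = sname, stringsAsFactors = FALSE)
  validate_taxonomy(df)
}

# Split dmp-dialect lines into trimmed field vectors.  Accepts both the
# canonical "\t|\t" separator and bare "|" with surrounding whitespace.
read_dmp <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- trimws(strsplit(ln, "|", fixed = TRUE)[[1L]])
    # a trailing "\t|" terminator leaves one empty trailing field
    if (length(f) && !nzchar(f[length(f)])) f <- f[-length(f)]
    f
  })
}

as_taxid <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v) || v < 1L) stop("invalid ", what, ": '", x, "'")
  v
}

validate_taxonomy <- function(df) {
  root <- df$taxid[df$taxid == df$parent_taxid]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one self-parent root node, found ",
         length(root))
  }
  unknown <- setdiff(df$parent_taxid, df$taxid)
  if (length(unknown)) {
    stop("parent taxid ", unknown[1L], " is not a node")
  }
  tree <- structure(list(nodes = df, root = root), class = "taxonomy_tree")
  # acyclicity: every node must reach the root in at most |nodes| steps
  pmap <- parent_map(tree)
  n <- nrow(df)
  for (t in df$taxid) {
    cur <- t
    steps <- 0L
    while (cur != root) {
      cur <- pmap[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxid ", t)
    }
  }
  tree
}

parent_map <- function(tree) {
  stats::setNames(as.list(tree$nodes$parent_taxid),
                  as.character(tree$nodes$taxid))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes, root taxid", x$root, "\n")
  invisible(x)
}

#' Write a taxonomy tree back to NCBI dump dialect
#'
#' Emits `nodes.dmp`- and `names.dmp`-dialect files (every name record with
#' class `"scientific name"`) such that [parse_taxonomy()] on the output
#' reconstructs an identical tree.
#'
#' @param tree a `taxonomy_tree`.
#' @param nodes_path,names_path output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_taxonomy <- function(tree, nodes_path, names_path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  nd <- tree$nodes
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nd$taxid, nd$parent_taxid,
                     nd$rank), nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", nd$taxid,
                     nd$scientific_name), names_path)
  invisible(list(nodes = nodes_path, names = names_path))
}

check_taxid <- function(tree, taxid) {
  if (!all(taxid %in% tree$nodes$taxid)) {
    stop("unknown taxid: ", setdiff(taxid, tree$nodes$taxid)[1L])
  }
}

#' Root-to-node lineage of a taxon
#'
#' @param tree a `taxonomy_tree`.
#' @param taxid a taxid present in the tree.
#' @return Integer vector of taxids from the root (first) down to `taxid`
#'   (last); consecutive elements are parent and child.
#' @export
lineage <- function(tree, taxid) {
  stopifnot(inherits(tree, "taxonomy_tree"), length(taxid) == 1L)
  taxid <- as.integer(taxid)
  check_taxid(tree, taxid)
  pmap <- parent_map(tree)
  path <- taxid
  cur <- taxid
  while (cur != tree$root) {
    cur <- pmap[[as.character(cur)]]
    path <- c(cur, path)
  }
  path
}

#' Ancestor of a taxon at a named rank
#'
#' Scans the lineage of `taxid` (self included) for the unique node whose
#' rank equals `rank`; ranks are compared exactly after lowercasing and
#' trimming, with no synonym table.
#'
#' @inheritParams lineage
#' @param rank a rank string such as `"family"` or `"class"`.
#' @return The matching ancestor's taxid, or `NA_integer_` when no ancestor
#'   carries the rank.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  rank <- norm_rank(rank)
  lin <- lineage(tree, taxid)
  ranks <- norm_rank(tree$nodes$rank[match(lin, tree$nodes$taxid)])
  hit <- which(ranks == rank)
  if (length(hit)) lin[hit[length(hit)]] else NA_integer_
}

norm_rank <- function(x) tolower(trimws(x))

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node present in every member's root-to-node lineage.  The
#' operation is commutative and associative; any set containing the root has
#' LCA equal to the root.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxids non-empty vector of taxids, all present in the tree.
#' @return A single taxid.
#' @export
lca <- function(tree, taxids) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("lca of an empty taxid set")
  check_taxid(tree, taxids)
  common <- lineage(tree, taxids[1L])
  for (t in taxids[-1L]) {
    lin <- lineage(tree, t)
    k <- min(length(common), length(lin))
    agree <- which(common[seq_len(k)] == lin[seq_len(k)])
    common <- common[seq_len(max(agree))]
  }
  common[length(common)]
}

#' Should a subject name be excluded from best-hit taxonomy?
#'
#' Marker-gene cataloging derives taxonomy from the best similarity hit
#' after skipping subjects from uncultured or unidentified organisms.  A
#' name is excluded when any exclusion term occurs in it,
#' case-insensitively.
#'
#' @param scientific_name character vector of names.
#' @param exclusion_terms terms whose presence excludes a name.
#' @return Logical vector, `TRUE` where the name is excluded.
#' @examples
#' is_excluded_name("uncultured bacterium")   # TRUE
#' is_excluded_name("Stappia indica")         # FALSE
#' @export
is_excluded_name <- function(scientific_name,
                             exclusion_terms = default_exclusion_terms()) {
  lo <- tolower(scientific_name)
  out <- rep(FALSE, length(lo))
  for (term in tolower(exclusion_terms)) {
    out <- out | grepl(term, lo, fixed = TRUE)
  }
  out
}

#' @rdname is_excluded_name
#' @export
default_exclusion_terms <- function() {
  c("uncultured", "unidentified", "environmental sample", "metagenome")
}

taxon_name <- function(tree, taxid) {
  tree$nodes$scientific_name[match(taxid, tree$nodes$taxid)]
}

taxon_rank <- function(tree, taxid) {
  tree$nodes$rank[match(taxid, tree$nodes$taxid)]
}
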