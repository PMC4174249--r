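#' Catalog rRNA marker contigs by best-hit taxonomy
#'
#' For a hit table produced against an rRNA database, keeps hits with
#' E-value strictly below the rRNA threshold, drops contigs flagged as
#' chimeric by an external tool, and derives each surviving contig's
#' taxonomy from its best remaining hit after skipping subjects whose
#' scientific name matches an exclusion term (uncultured, unidentified,
#' ...).  Unresolved hits cannot be name-checked and are skipped as well.
#'
#' Chimera detection itself is out of scope — the published workflow ran
#' dedicated tools for it — so flags are consumed as a simple
#' contig-to-logical map.
#'
#' @param table a resolved `hit_table` from an rRNA-database search.
#' @param tree a `taxonomy_tree`.
#' @param config a `pipeline_config` (uses `evalue_max_rrna` and
#'   `exclusion_terms`).
#' @param chimera_flags named logical vector keyed by contig id (`TRUE` =
#'   chimeric), or `NULL` for none.
#' @return data.frame of marker records: `contig_id`, `best_subject`,
#'   `best_taxid`, `best_name`, `evalue`, `chimera_flag` (always `FALSE`
#'   for surviving contigs).
#' @export
extract_rrna_contigs <- function(table, tree, config = pipeline_config(),
                                 chimera_flags = NULL) {
  h <- filter_hits(table, config$evalue_max_rrna)
  if (!is.null(chimera_flags)) {
    bad <- names(chimera_flags)[chimera_flags %in% TRUE]
    h <- h[!(h$qseqid %in% bad), , drop = FALSE]
  }
  groups <- split(seq_len(nrow(h)), h$qseqid)
  rows <- lapply(groups, function(ix) {
    g <- usable_hits(h[ix, , drop = FALSE])
    if (nrow(g) == 0L) return(NULL)
    nm <- taxon_name(tree, g$staxid)
    g <- g[!is_excluded_name(nm, config$exclusion_terms), , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    data.frame(contig_id = g$qseqid[1L], best_subject = g$sseqid[1L],
               best_taxid = g$staxid[1L],
               best_name = taxon_name(tree, g$staxid[1L]),
               evalue = g$evalue[1L], chimera_flag = FALSE,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) {
    out <- do.call(rbind, rows)
  } else {
    out <- data.frame(contig_id = character(0), best_subject = character(0),
                      best_taxid = integer(0), best_name = character(0),
                      evalue = numeric(0), chimera_flag = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Load an accession-to-gene map from gene2accession / gene_info dialects
#'
#' Both inputs are tab-separated with `#`-comment headers.  The
#' gene2accession-dialect stream supplies (GeneID, nucleotide accession)
#' pairs; `"-"` placeholder accessions are skipped.  The gene_info-dialect
#' stream supplies (GeneID, Symbol).  Column positions are configurable
#' because real dumps carry many more columns than the toy fixtures.
#' Accessions are keyed both with and without their `.N` version suffix.
#'
#' A GeneID present in gene2accession but absent from gene_info keeps its
#' entry with an empty symbol; such rows are tallied in the attribute
#' `n_missing_symbol`.
#'
#' @param gene2accession path or lines of the accession map.
#' @param gene_info path or lines of the gene table.
#' @param g2a_cols integer positions of `geneid` and `accession` columns
#'   in gene2accession (defaults: 2 and 4, the dump layout).
#' @param gi_cols integer positions of `geneid` and `symbol` in gene_info.
#' @return data.frame `accession`, `gene_id`, `symbol` with one row per
#'   distinct keyed accession form.
#' @export
load_gene_map <- function(gene2accession, gene_info,
                          g2a_cols = c(geneid = 2L, accession = 4L),
                          gi_cols = c(geneid = 2L, symbol = 3L)) {
  g2a <- read_tsv_fields(gene2accession)
  gi <- read_tsv_fields(gene_info)
  gid <- vapply(g2a, `[`, "", g2a_cols[["geneid"]])
  acc <- vapply(g2a, `[`, "", g2a_cols[["accession"]])
  keep <- acc != "-" & nzchar(acc)
  gid <- gid[keep]
  acc <- acc[keep]
  sym_gid <- vapply(gi, `[`, "", gi_cols[["geneid"]])
  sym <- vapply(gi, `[`, "", gi_cols[["symbol"]])
  symbol <- sym[match(gid, sym_gid)]
  missing <- is.na(symbol)
  symbol[missing] <- ""
  stripped <- sub("\\.[0-9]+$", "", acc)
  out <- data.frame(accession = c(acc, stripped),
                    gene_id = c(gid, gid), symbol = c(symbol, symbol),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_symbol") <- sum(missing)
  out
}

read_tsv_fields <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read the functional gene catalog
#'
#' Editable TSV with columns `gene_symbol`, `category`, `accessions`
#' (comma-separated member accessions).  The shipped default
#' (`system.file("extdata", "gene_catalog.tsv", package = "contigtax")`)
#' covers the perchlorate-reduction cluster pcrA-D, the chlorite dismutase
#' cld, and respiratory/dissimilatory nitrate reductase genes
#' (narG, narH, napA).
#'
#' @param path catalog TSV path.
#' @return data.frame `gene_symbol`, `category`, `accessions` plus list
#'   column `members`.
#' @export
read_gene_catalog <- function(path = system.file("extdata",
                                                 "gene_catalog.tsv",
                                                 package = "contigtax")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  stopifnot(all(c("gene_symbol", "category", "accessions") %in% names(df)))
  if (anyDuplicated(df$gene_symbol)) {
    stop("duplicate gene_symbol in catalog: ",
         df$gene_symbol[duplicated(df$gene_symbol)][1L])
  }
  df$members <- lapply(strsplit(df$accessions, ","), trimws)
  if (any(lengths(df$members) == 0L)) stop("catalog entry with no accessions")
  df
}

#' Annotate contigs with cataloged functional genes
#'
#' Walks each contig's hits best-first.  A hit annotates when its subject
#' accession (versioned or not) is a member accession of a catalog entry,
#' or maps through the gene map to a symbol present in the catalog.  Per
#' contig and per category, the best such hit wins and at most one
#' annotation is emitted, so re-annotating already-annotated contigs is
#' idempotent.
#'
#' @param table an E-value-filtered `hit_table`.
#' @param gene_map data.frame from [load_gene_map()] (may be `NULL`).
#' @param catalog data.frame from [read_gene_catalog()].
#' @param source_label label of the annotation source (one column of the
#'   gene-taxon table), e.g. the database searched.
#' @return data.frame: `contig_id`, `gene_symbol`, `category`,
#'   `subject_accession`, `bitscore`, `evalue`, `source`.
#' @export
annotate_genes <- function(table, gene_map, catalog,
                           source_label = "blastn") {
  member_of <- member_lookup(catalog)
  sym_cat <- stats::setNames(catalog$category, catalog$gene_symbol)
  h <- sort_hit_table(table)
  symbols <- symbol_for_accession(h$sseqid, member_of, gene_map, sym_cat)
  keep <- !is.na(symbols)
  h <- h[keep, , drop = FALSE]
  symbols <- symbols[keep]
  if (nrow(h) == 0L) return(empty_annotation())
  cat_of <- unname(sym_cat[symbols])
  first <- !duplicated(paste(h$qseqid, cat_of, sep = "\r"))
  data.frame(contig_id = h$qseqid[first], gene_symbol = symbols[first],
             category = cat_of[first],
             subject_accession = h$sseqid[first],
             bitscore = h$bitscore[first], evalue = h$evalue[first],
             source = source_label, stringsAsFactors = FALSE,
             row.names = NULL)
}

empty_annotation <- function() {
  data.frame(contig_id = character(0), gene_symbol = character(0),
             category = character(0), subject_accession = character(0),
             bitscore = numeric(0), evalue = numeric(0),
             source = character(0), stringsAsFactors = FALSE)
}

member_lookup <- function(catalog) {
  sym <- rep(catalog$gene_symbol, lengths(catalog$members))
  acc <- unlist(catalog$members, use.names = FALSE)
  both <- c(acc, sub("\\.[0-9]+$", "", acc))
  stats::setNames(c(sym, sym), both)
}

symbol_for_accession <- function(acc, member_of, gene_map, sym_cat) {
  out <- unname(member_of[acc])
  stripped <- sub("\\.[0-9]+$", "", acc)
  na <- is.na(out)
  out[na] <- unname(member_of[stripped[na]])
  if (!is.null(gene_map)) {
    na <- is.na(out)
    mapped <- gene_map$symbol[match(acc, gene_map$accession)]
    mapped2 <- gene_map$symbol[match(stripped, gene_map$accession)]
    mapped[is.na(mapped)] <- mapped2[is.na(mapped)]
    cataloged <- !is.na(mapped) & mapped %in% names(sym_cat)
    out[na & cataloged] <- mapped[na & cataloged]
  }
  out
}

#' Tabulate gene annotations by taxonomic group
#'
#' Cross-tabulates the annotated contigs of one functional category:
#' rows are taxonomic groups at `group_rank` (derived from each contig's
#' assignment), columns are annotation sources, cells are contig counts.
#' Contigs that are unassigned or lack an ancestor at the rank fall into
#' the `"Undefined"` row; a `"Total"` row holding the column sums is
#' appended.  Columns are independent tallies per source — a contig seen
#' by two sources counts once in each column.
#'
#' @param annotations data.frame from [annotate_genes()] (possibly several
#'   sources row-bound together).
#' @param assignments data.frame from [assign_contigs()] covering the
#'   annotated contigs.
#' @param tree a `taxonomy_tree`.
#' @param group_rank rank of the row groups (default `"class"`).
#' @param category the functional category to tabulate.
#' @return data.frame with column `group` followed by one integer column
#'   per source; last row is `"Total"`.
#' @export
tabulate_gene_taxonomy <- function(annotations, assignments, tree,
                                   group_rank = "class", category) {
  ann <- annotations[annotations$category == category, , drop = FALSE]
  sources <- sort(unique(annotations$source))
  if (length(sources) == 0L) sources <- "annotated"
  tax <- assignments$taxid[match(ann$contig_id, assignments$contig_id)]
  grp <- rep("Undefined", nrow(ann))
  has <- !is.na(tax)
  if (any(has)) {
    anc <- vapply(tax[has], function(t) ancestor_at_rank(tree, t, group_rank), 1L)
    nm <- taxon_name(tree, anc)
    grp[has][!is.na(anc)] <- nm[!is.na(anc)]
  }
  groups <- c(sort(unique(grp[grp != "Undefined"])), "Undefined")
  counts <- sapply(sources, function(s) {
    g <- grp[ann$source == s]
    as.integer(table(factor(g, levels = groups)))
  })
  counts <- matrix(counts, nrow = length(groups),
                   dimnames = list(NULL, sources))
  out <- data.frame(group = groups, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  total <- data.frame(group = "Total",
                      t(colSums(counts)), check.names = FALSE,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}
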