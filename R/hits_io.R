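#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline.  Defaults reflect the
#' published analysis the pipeline reimplements: hits against comprehensive
#' nucleotide/protein databases are kept at E-value < 1e-10, hits against
#' rRNA databases at E-value < 1e-5 (both strict inequalities), contigs
#' shorter than 100 nt are dropped, abundance plots keep the most abundant
#' families up to 90% cumulative proportion, profiles are reported at the
#' family rank and grouped by class.
#'
#' @param evalue_max_global E-value cutoff for nt/nr-class hit files.
#' @param evalue_max_rrna E-value cutoff for rRNA-database hit files.
#' @param min_contig_len minimum contig length retained (inclusive).
#' @param cumulative_frac cumulative proportion cutoff in (0, 1].
#' @param lca_top_percent bitscore window (percent below the best resolved
#'   bitscore) admitting hits into the LCA candidate set.
#' @param report_rank rank at which abundance profiles are reported.
#' @param group_rank rank used to group families / tabulate gene hits.
#' @param exclusion_terms subject-name terms excluded from best-hit
#'   taxonomy (see [is_excluded_name()]).
#' @param rng_seed integer seed driving all stochastic fixture generation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_max_global = 1e-10,
                            evalue_max_rrna = 1e-5,
                            min_contig_len = 100L,
                            cumulative_frac = 0.90,
                            lca_top_percent = 10.0,
                            report_rank = "family",
                            group_rank = "class",
                            exclusion_terms = default_exclusion_terms(),
                            rng_seed = 1L) {
  stopifnot(evalue_max_global > 0, evalue_max_rrna > 0,
            cumulative_frac > 0, cumulative_frac <= 1,
            lca_top_percent >= 0, min_contig_len >= 0)
  structure(list(evalue_max_global = evalue_max_global,
                 evalue_max_rrna = evalue_max_rrna,
                 min_contig_len = as.integer(min_contig_len),
                 cumulative_frac = cumulative_frac,
                 lca_top_percent = lca_top_percent,
                 report_rank = report_rank,
                 group_rank = group_rank,
                 exclusion_terms = exclusion_terms,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are an error (they usually indicate a typo); absent keys
#' fall back to the [pipeline_config()] defaults.
#'
#' @param path YAML file with flat `key: value` pairs.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field: ", bad[1L])
  do.call(pipeline_config, vals)
}

hit_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
hit_columns_ext <- c(hit_columns, "nident", "staxid")
hit_numeric <- setdiff(hit_columns_ext, c("qseqid", "sseqid"))

#' Read a tabular similarity-search hit file
#'
#' Parses the 12-column tab-separated dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`) or the
#' extended dialect with two trailing columns `nident` (identical
#' positions) and `staxid` (subject taxid).  Comment lines starting with
#' `#` are skipped and gzip-compressed input is read transparently.
#' Coordinates are kept 1-based inclusive exactly as in the input;
#' reverse-strand subject matches may have `sstart > send`.
#'
#' Rows are returned grouped by query with each group ordered by descending
#' bitscore, ties broken by ascending E-value then lexicographic subject
#' accession.  This ordering is restored after every operation that edits
#' the table.
#'
#' @param path file path (optionally `.gz`), or a character vector of lines.
#' @param dialect `"auto"` (default; decided by the first data row),
#'   `"base"` (12 columns) or `"extended"` (14 columns).
#' @return A data.frame of class `hit_table` with the extended-dialect
#'   columns (`nident`/`staxid` are `NA` when absent from the input) plus
#'   `unresolved`, set by [resolve_taxids()].
#' @export
read_hit_table <- function(path, dialect = c("auto", "base", "extended")) {
  dialect <- match.arg(dialect)
  if (length(path) == 1L && file.exists(path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
  } else {
    lines <- path
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hit_table())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  want <- switch(dialect,
                 base = 12L,
                 extended = 14L,
                 auto = if (ncols[1L] %in% c(12L, 14L)) ncols[1L] else
                   stop("line ", lineno[1L], ": expected 12 or 14 columns, found ",
                        ncols[1L]))
  bad <- which(ncols != want)
  if (length(bad)) {
    stop("line ", lineno[bad[1L]], ": expected ", want,
         " columns, found ", ncols[bad[1L]])
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  df <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                   stringsAsFactors = FALSE)
  numcols <- if (want == 14L) hit_numeric else
    setdiff(hit_numeric, c("nident", "staxid"))
  for (i in seq_along(numcols)) {
    raw <- m[, i + 2L]
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("line ", lineno[j], ": non-numeric value '", raw[j],
           "' in column ", numcols[i])
    }
    df[[numcols[i]]] <- v
  }
  if (want == 12L) {
    df$nident <- NA_real_
    df$staxid <- NA_real_
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  df$nident <- ifelse(is.na(df$nident), NA_integer_, as.integer(df$nident))
  df$staxid <- ifelse(is.na(df$staxid), NA_integer_, as.integer(df$staxid))
  df$unresolved <- NA
  validate_hits(df)
  sort_hit_table(df)
}

empty_hit_table <- function() {
  df <- data.frame(qseqid = character(0), sseqid = character(0),
                   stringsAsFactors = FALSE)
  for (cc in hit_numeric) df[[cc]] <- numeric(0)
  df$unresolved <- logical(0)
  class(df) <- c("hit_table", "data.frame")
  df
}

validate_hits <- function(df) {
  if (any(df$qstart > df$qend)) {
    stop("qstart > qend at row ", which(df$qstart > df$qend)[1L])
  }
  has <- !is.na(df$nident)
  if (any(df$nident[has] > df$length[has])) {
    stop("nident exceeds alignment length at row ",
         which(has)[df$nident[has] > df$length[has]][1L])
  }
  dev <- abs(df$pident[has] - 100 * df$nident[has] / df$length[has])
  if (any(dev > 0.5)) {
    stop("pident inconsistent with nident/length at row ",
         which(has)[dev > 0.5][1L])
  }
  invisible(df)
}

# Canonical ordering: by query, then descending bitscore, ascending
# E-value, lexicographic subject accession (a convention for determinism).
sort_hit_table <- function(df) {
  o <- order(df$qseqid, -df$bitscore, df$evalue, df$sseqid, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("hit_table", class(df)))
  df
}

#' Write a hit table in tabular dialect
#'
#' @param table a `hit_table`.
#' @param path output path.
#' @param dialect `"extended"` (default, round-trips `nident`/`staxid`) or
#'   `"base"`.
#' @export
write_hit_table <- function(table, path, dialect = c("extended", "base")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "extended") hit_columns_ext else hit_columns
  out <- table[, cols, drop = FALSE]
  out$evalue <- format_evalue(out$evalue)
  lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# %g keeps round-trip fidelity for both tiny E-values and exact zeros
format_evalue <- function(x) sprintf("%.6g", x)

#' Resolve subject accessions to taxids
#'
#' Fills `staxid` for every hit whose subject accession is in the
#' accession-to-taxid map (exact match first, then with a trailing `.N`
#' version suffix stripped) and whose taxid exists in the tree.  Hits whose
#' input `staxid` already points at a tree node keep it when the map has no
#' entry.  Anything else is flagged `unresolved`; unresolved hits are
#' retained and counted (attribute `n_unresolved`), never dropped.
#'
#' @param table a `hit_table`.
#' @param acc2taxid named integer vector (names are accessions) or a
#'   two-column data.frame `accession`, `taxid`.
#' @param tree a `taxonomy_tree`.
#' @return The table with `staxid` and `unresolved` updated.
#' @export
resolve_taxids <- function(table, acc2taxid, tree) {
  if (is.data.frame(acc2taxid)) {
    acc2taxid <- stats::setNames(as.integer(acc2taxid$taxid),
                                 acc2taxid$accession)
  }
  known <- tree$nodes$taxid
  acc <- table$sseqid
  tid <- unname(acc2taxid[acc])
  stripped <- sub("\\.[0-9]+$", "", acc)
  fb <- is.na(tid)
  tid[fb] <- unname(acc2taxid[stripped[fb]])
  # an input staxid that is a valid tree node survives when unmapped
  keep_own <- is.na(tid) & !is.na(table$staxid) & table$staxid %in% known
  tid[keep_own] <- table$staxid[keep_own]
  ok <- !is.na(tid) & tid %in% known
  table$staxid <- ifelse(ok, as.integer(tid), NA_integer_)
  table$unresolved <- !ok
  attr(table, "n_unresolved") <- sum(!ok)
  sort_hit_table(table)
}

#' Filter hits by E-value
#'
#' Retains exactly the hits with E-value strictly below `evalue_max` (a hit
#' at exactly the threshold is removed), preserving group ordering.
#'
#' @param table a `hit_table`.
#' @param evalue_max positive cutoff.
#' @return The filtered `hit_table`.
#' @export
filter_hits <- function(table, evalue_max) {
  stopifnot(evalue_max > 0)
  out <- table[table$evalue < evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("hit_table", class(out)))
  out
}

#' Identity count of a hit
#'
#' The abundance weight unit is the number of identical alignment columns.
#' When the input dialect carries `nident` it is used verbatim; otherwise
#' the count is recovered as `round(pident * length / 100)` with half-up
#' rounding.
#'
#' @param hit a `hit_table` (or any data.frame with `pident`, `length`,
#'   `nident`); vectorised over rows.
#' @return Integer vector of identity counts.
#' @export
infer_n_ident <- function(hit) {
  est <- as.integer(floor(hit$pident * hit$length / 100 + 0.5))
  ifelse(!is.na(hit$nident), as.integer(hit$nident), est)
}

#' Read an accession-to-taxid map
#'
#' Two-column tab-separated file: accession, taxid.  Lines starting `#`
#' are skipped.
#'
#' @param path TSV path.
#' @return data.frame with columns `accession`, `taxid`.
#' @export
read_acc2taxid <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("accession", "taxid"))
  df$taxid <- as.integer(df$taxid)
  df
}
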