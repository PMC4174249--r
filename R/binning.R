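#' Assign a contig to a taxon by Unique Best Hit (UBH)
#'
#' Operates on the hits of a single contig (taxid-resolved and
#' E-value-filtered).  Hit order is recomputed internally, so the result is
#' invariant to input permutation.  The highest-bitscore stratum containing
#' at least one resolved hit decides the call: a unique resolved top hit
#' assigns its subject taxon, several resolved hits tied at the top
#' bitscore assign the LCA of their taxa.  Strata whose hits are all
#' unresolved are skipped; a group with no resolved hit (or no hit at all)
#' is unassigned.
#'
#' The assignment weight is the identity count ([infer_n_ident()]) of the
#' best hit; on ties, the maximum identity count among the tied hits.  One
#' weight per contig — identities are never summed across hits, so each
#' contig is counted once in abundance profiles.
#'
#' @param hits_for_contig a `hit_table` subset holding one contig's hits
#'   (may be empty).
#' @param tree a `taxonomy_tree`.
#' @return A one-row data.frame: `contig_id`, `taxid` (`NA` when
#'   unassigned), `method`, `weight`, `n_evidence`, and the contributing
#'   subject accessions in the attribute-free list column `evidence`.
#' @export
assign_ubh <- function(hits_for_contig, tree) {
  h <- usable_hits(hits_for_contig)
  if (nrow(h) == 0L) {
    return(unassigned_row(contig_of(hits_for_contig), "UBH"))
  }
  top <- h[h$bitscore == h$bitscore[1L], , drop = FALSE]
  taxid <- if (nrow(top) == 1L) top$staxid else lca(tree, top$staxid)
  assignment_row(h$qseqid[1L], taxid, "UBH",
                 max(infer_n_ident(top)), top$sseqid)
}

#' Assign a contig to a taxon by Lowest Common Ancestor (LCA)
#'
#' The candidate set is every resolved hit whose bitscore is at least
#' `(1 - top_percent/100)` times the best resolved bitscore of the contig;
#' the call is the LCA of the candidates' taxa and the weight the maximum
#' identity count among them.  With `top_percent = 0` and a unique best
#' hit this reduces to [assign_ubh()].
#'
#' @inheritParams assign_ubh
#' @param top_percent non-negative width of the bitscore window, in percent.
#' @return As [assign_ubh()], with `method = "LCA"`.
#' @export
assign_lca <- function(hits_for_contig, tree, top_percent = 10) {
  stopifnot(top_percent >= 0)
  h <- usable_hits(hits_for_contig)
  if (nrow(h) == 0L) {
    return(unassigned_row(contig_of(hits_for_contig), "LCA"))
  }
  cut <- (1 - top_percent / 100) * h$bitscore[1L]
  cand <- h[h$bitscore >= cut, , drop = FALSE]
  assignment_row(h$qseqid[1L], lca(tree, cand$staxid), "LCA",
                 max(infer_n_ident(cand)), cand$sseqid)
}

# resolved hits of one contig in canonical order
usable_hits <- function(h) {
  if (nrow(h) == 0L) return(h)
  if (length(unique(h$qseqid)) > 1L) {
    stop("assignment operates on the hits of a single contig")
  }
  h <- sort_hit_table(h)
  # unresolved may be NA when resolve_taxids was not run; a present staxid
  # then counts as resolved
  ok <- !is.na(h$staxid) & !(h$unresolved %in% TRUE)
  h[ok, , drop = FALSE]
}

contig_of <- function(h) {
  if (nrow(h)) h$qseqid[1L] else NA_character_
}

assignment_row <- function(contig_id, taxid, method, weight, evidence) {
  df <- data.frame(contig_id = contig_id, taxid = as.integer(taxid),
                   method = method, weight = as.integer(weight),
                   n_evidence = length(evidence), stringsAsFactors = FALSE)
  df$evidence <- list(evidence)
  df
}

unassigned_row <- function(contig_id, method) {
  df <- data.frame(contig_id = contig_id, taxid = NA_integer_,
                   method = method, weight = 0L, n_evidence = 0L,
                   stringsAsFactors = FALSE)
  df$evidence <- list(character(0))
  df
}

#' Assign every contig in a hit table
#'
#' Splits a resolved, filtered hit table by query and applies
#' [assign_ubh()] or [assign_lca()] per contig.  Contigs named in
#' `contig_ids` but absent from the table come out unassigned with weight
#' zero, so a community's full contig set can be accounted for.
#'
#' @param table a `hit_table`.
#' @param tree a `taxonomy_tree`.
#' @param method `"ubh"` or `"lca"`.
#' @param top_percent LCA bitscore window (ignored for UBH).
#' @param contig_ids optional character vector of all contig ids.
#' @return data.frame of assignments, one row per contig.
#' @export
assign_contigs <- function(table, tree, method = c("ubh", "lca"),
                           top_percent = 10, contig_ids = NULL) {
  method <- match.arg(method)
  groups <- split(seq_len(nrow(table)), table$qseqid)
  res <- lapply(groups, function(ix) {
    h <- table[ix, , drop = FALSE]
    if (method == "ubh") assign_ubh(h, tree) else
      assign_lca(h, tree, top_percent)
  })
  out <- if (length(res)) do.call(rbind, res) else
    unassigned_row("x", toupper(method))[0L, , drop = FALSE]
  missing <- setdiff(contig_ids, out$contig_id)
  if (length(missing)) {
    extra <- do.call(rbind, lapply(missing, unassigned_row,
                                   method = toupper(method)))
    out <- rbind(out, extra)
  }
  out <- out[order(out$contig_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
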