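#' Identity-weighted abundance profile at a rank
#'
#' Each assigned contig contributes its identity-count weight to its
#' ancestor at the requested rank.  The proportion of a taxon is the
#' number of identities in all contigs assigned to it divided by the
#' number of identities in all contigs assigned to any taxon resolved at
#' that rank.  Contigs that are unassigned, or whose taxon has no ancestor
#' at the rank (e.g. a call above the family level when profiling
#' families), accumulate into `unassigned_weight` — reported alongside,
#' never silently dropped, and excluded from the proportion denominator.
#'
#' @param assignments data.frame from [assign_contigs()].
#' @param tree a `taxonomy_tree`.
#' @param rank rank string, e.g. `"family"`.
#' @return An `abundance_profile`: list with `rank`, `entries` (data.frame
#'   `taxid`, `name`, `weight`, `proportion`, sorted by descending
#'   proportion then ascending taxid) and `unassigned_weight`.
#' @export
compute_profile <- function(assignments, tree, rank) {
  a <- assignments
  anc <- rep(NA_integer_, nrow(a))
  assigned <- !is.na(a$taxid)
  if (any(assigned)) {
    uniq <- unique(a$taxid[assigned])
    up <- vapply(uniq, function(t) ancestor_at_rank(tree, t, rank), 1L)
    anc[assigned] <- up[match(a$taxid[assigned], uniq)]
  }
  ok <- !is.na(anc)
  unassigned_weight <- sum(a$weight[!ok])
  if (!any(ok)) {
    entries <- data.frame(taxid = integer(0), name = character(0),
                          weight = integer(0), proportion = numeric(0))
  } else {
    w <- tapply(a$weight[ok], anc[ok], sum)
    entries <- data.frame(taxid = as.integer(names(w)),
                          weight = as.integer(w),
                          stringsAsFactors = FALSE)
    entries$name <- taxon_name(tree, entries$taxid)
    entries$proportion <- entries$weight / sum(entries$weight)
    entries <- entries[order(-entries$proportion, entries$taxid), c("taxid", "name", "weight", "proportion")]
    rownames(entries) <- NULL
  }
  structure(list(rank = norm_rank(rank), entries = entries,
                 unassigned_weight = as.integer(unassigned_weight)),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("abundance_profile at rank '", x$rank, "': ", nrow(x$entries),
      " taxa, unassigned weight ", x$unassigned_weight, "\n", sep = "")
  if (nrow(x$entries)) print(utils::head(x$entries, 10L))
  invisible(x)
}

#' Most abundant taxa up to a cumulative proportion
#'
#' Entries are ranked by descending proportion (ties by ascending taxid)
#' and the shortest prefix whose proportions sum to at least `frac` is
#' returned — the selection rule behind "families contributing to the 90%
#' of cumulative percentage" displays.
#'
#' @param profile an `abundance_profile`.
#' @param frac cumulative cutoff in (0, 1].
#' @return Integer vector of taxids (possibly empty).
#' @export
cumulative_select <- function(profile, frac) {
  stopifnot(frac > 0, frac <= 1)
  e <- profile$entries
  if (nrow(e) == 0L) return(integer(0))
  e <- e[order(-e$proportion, e$taxid), , drop = FALSE]
  k <- which(cumsum(e$proportion) >= frac - 1e-12)[1L]
  e$taxid[seq_len(k)]
}

#' Compare two abundance profiles
#'
#' Takes the union of taxa of two same-rank profiles and reports, per
#' taxon, the proportion in each community (0 where absent), the mean
#' proportion and the difference (B minus A).  Two orderings are
#' available: `"by_mean"` sorts by mean proportion alone;
#' `"by_class"` groups taxa by their ancestor at `class_rank` (classes
#' ordered by their summed mean proportion) and sorts by mean within each
#' class — the layout of stacked-by-class abundance figures.
#'
#' @param profile_a,profile_b `abundance_profile`s at the same rank.
#' @param tree a `taxonomy_tree` (needed to resolve class ancestors; may be
#'   `NULL` for `"by_mean"`).
#' @param ordering `"by_mean"` or `"by_class"`.
#' @param class_rank grouping rank for `"by_class"`.
#' @return data.frame: `taxid`, `name`, `class_name`, `proportion_a`,
#'   `proportion_b`, `mean`, `diff`.
#' @export
compare_profiles <- function(profile_a, profile_b, tree = NULL,
                             ordering = c("by_mean", "by_class"),
                             class_rank = "class") {
  ordering <- match.arg(ordering)
  if (!identical(profile_a$rank, profile_b$rank)) {
    stop("profiles are at different ranks: '", profile_a$rank, "' vs '",
         profile_b$rank, "'")
  }
  taxids <- sort(union(profile_a$entries$taxid, profile_b$entries$taxid))
  pa <- profile_a$entries$proportion[match(taxids, profile_a$entries$taxid)]
  pb <- profile_b$entries$proportion[match(taxids, profile_b$entries$taxid)]
  pa[is.na(pa)] <- 0
  pb[is.na(pb)] <- 0
  name <- profile_a$entries$name[match(taxids, profile_a$entries$taxid)]
  nb <- profile_b$entries$name[match(taxids, profile_b$entries$taxid)]
  name[is.na(name)] <- nb[is.na(name)]
  cls <- rep(NA_character_, length(taxids))
  if (!is.null(tree)) {
    ct <- vapply(taxids, function(t) ancestor_at_rank(tree, t, class_rank), 1L)
    cls <- taxon_name(tree, ct)
  }
  out <- data.frame(taxid = taxids, name = name, class_name = cls,
                    proportion_a = pa, proportion_b = pb,
                    mean = (pa + pb) / 2, diff = pb - pa,
                    stringsAsFactors = FALSE)
  if (ordering == "by_mean") {
    out <- out[order(-out$mean, out$taxid), , drop = FALSE]
  } else {
    if (is.null(tree)) stop("ordering 'by_class' needs a taxonomy tree")
    csum <- tapply(out$mean, out$class_name, sum)
    key <- -as.numeric(csum[out$class_name])
    key[is.na(key)] <- Inf   # classless taxa sink to the bottom
    out <- out[order(key, out$class_name, -out$mean, out$taxid), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Assembly statistics of a contig set
#'
#' Summary statistics over contig lengths at least `min_len` nucleotides
#' (the assembler's minimum contig size; the floor is inclusive).  N50 is
#' the largest length L such that contigs of length >= L together contain
#' at least half of the retained nucleotides.
#'
#' @param lengths positive integer vector of contig lengths.
#' @param min_len inclusive length floor (default 100).
#' @return A list of class `contig_stats`: `n_contigs`, `total_nt`,
#'   `longest`, `shortest`, `mean`, `n50`.
#' @examples
#' contig_stats(c(100, 200, 300, 400, 500))$n50  # 400
#' @export
contig_stats <- function(lengths, min_len = 100L) {
  lengths <- as.integer(lengths)
  stopifnot(all(lengths > 0L))
  keep <- lengths[lengths >= min_len]
  if (length(keep) == 0L) {
    stop("no contigs of length >= ", min_len)
  }
  s <- sort(keep, decreasing = TRUE)
  total <- sum(as.numeric(s))
  n50 <- s[which(cumsum(as.numeric(s)) >= total / 2)[1L]]
  structure(list(n_contigs = length(keep), total_nt = total,
                 longest = max(keep), shortest = min(keep),
                 mean = mean(keep), n50 = n50),
            class = "contig_stats")
}

#' @export
print.contig_stats <- function(x, ...) {
  cat(sprintf(paste0("contigs: %d  total nt: %.0f  longest: %d  ",
                     "shortest: %d  mean: %.1f  N50: %d\n"),
              x$n_contigs, x$total_nt, x$longest, x$shortest, x$mean,
              x$n50))
  invisible(x)
}

#' Write / read an abundance profile as TSV
#'
#' Columns: `rank`, `taxid`, `name`, `class_name`, `weight`, `proportion`;
#' the unassigned weight travels in a `# unassigned_weight:` header
#' comment so the file round-trips.
#'
#' @param profile an `abundance_profile`.
#' @param path output path.
#' @param tree optional `taxonomy_tree` used to fill `class_name`.
#' @param class_rank grouping rank recorded per row.
#' @export
write_profile_tsv <- function(profile, path, tree = NULL,
                              class_rank = "class") {
  e <- profile$entries
  cls <- rep(NA_character_, nrow(e))
  if (!is.null(tree) && nrow(e)) {
    ct <- vapply(e$taxid, function(t) ancestor_at_rank(tree, t, class_rank), 1L)
    cls <- taxon_name(tree, ct)
  }
  out <- data.frame(rank = rep(profile$rank, nrow(e)), taxid = e$taxid,
                    name = e$name, class_name = cls, weight = e$weight,
                    proportion = sprintf("%.10g", e$proportion),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unassigned_weight: %d", profile$unassigned_weight),
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  uw <- as.integer(sub("# unassigned_weight:\\s*", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  entries <- data.frame(taxid = as.integer(df$taxid), name = df$name,
                        weight = as.integer(df$weight),
                        proportion = as.numeric(df$proportion),
                        stringsAsFactors = FALSE)
  entries <- entries[, c("taxid", "name", "weight", "proportion")]
  structure(list(rank = if (nrow(df)) df$rank[1L] else NA_character_,
                 entries = entries, unassigned_weight = uw,
                 class_name = df$class_name),
            class = "abundance_profile")
}
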