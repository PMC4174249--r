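#' Generate a toy taxonomy with a fixed rank skeleton
#'
#' Builds a rooted tree with the rank skeleton
#' root -> superkingdom -> class -> order -> family -> genus -> species:
#' one order per family, `genera_per_family` genera per family, one
#' species per genus.  Families are distributed round-robin over two
#' classes (one class when `n_families == 1`) so class-level grouping is
#' exercised.  Construction is deterministic — the same arguments always
#' yield byte-identical dump files.
#'
#' @param n_families number of families (>= 1).
#' @param genera_per_family genera under each family (>= 1).
#' @param seed kept for interface symmetry with the stochastic
#'   generators; the construction itself is deterministic.
#' @param dir optional directory; when given, `nodes.dmp` / `names.dmp`
#'   are written there.
#' @return A `taxonomy_tree`.  Leaf (species) taxids are in
#'   `attr(tree, "leaves")`, one vector element per species, ordered by
#'   family then genus.
#' @export
generate_taxonomy <- function(n_families, genera_per_family, seed = 1L,
                              dir = NULL) {
  stopifnot(n_families >= 1, genera_per_family >= 1)
  nodes <- list()
  add <- function(taxid, parent, rank, name) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      taxid = taxid, parent_taxid = parent, rank = rank,
      scientific_name = name, stringsAsFactors = FALSE)
    taxid
  }
  nid <- 0L
  nxt <- function() { nid <<- nid + 1L; nid }
  root <- add(nxt(), 1L, "no rank", "root")
  sk <- add(nxt(), root, "superkingdom", "Bacteria")
  n_classes <- if (n_families > 1L) 2L else 1L
  classes <- vapply(seq_len(n_classes), function(k)
    add(nxt(), sk, "class", sprintf("Synclass%02d", k)), 1L)
  leaves <- integer(0)
  for (f in seq_len(n_families)) {
    cl <- classes[((f - 1L) %% n_classes) + 1L]
    ord <- add(nxt(), cl, "order", sprintf("Synorder%02d", f))
    fam <- add(nxt(), ord, "family", sprintf("Synfamily%02d", f))
    for (g in seq_len(genera_per_family)) {
      gen <- add(nxt(), fam, "genus", sprintf("Syngenus%02d_%02d", f, g))
      sp <- add(nxt(), gen, "species",
                sprintf("Syngenus%02d_%02d species", f, g))
      leaves <- c(leaves, sp)
    }
  }
  df <- do.call(rbind, nodes)
  tree <- validate_taxonomy(df)
  attr(tree, "leaves") <- leaves
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_taxonomy(tree, file.path(dir, "nodes.dmp"),
                   file.path(dir, "names.dmp"))
  }
  tree
}

#' Specification of a synthetic community
#'
#' Ground-truth definition driving fixture generation.  Contig sources are
#' drawn from `proportions` over leaf `taxa`; contig lengths follow a
#' log-normal (median `length_median`, log-sd `length_sigma`) truncated at
#' `min_contig_len`, matching the short-contig regime of 36-mer-read
#' assemblies (median around 230 nt).  Each contig receives one on-target
#' hit with identity around `identity_mean`; with probability
#' `off_target_rate` it also hits a relative, losing `identity_decay`
#' identity points per taxonomic rank step between the true source and the
#' relative, and always at a strictly lower bitscore than the on-target
#' hit.  Bitscores are affine in the identity count
#' (`bitscore_slope * n_ident + bitscore_intercept`) with Gaussian noise;
#' E-values follow the strictly monotone map
#' `E = qlen * 2^(-bitscore) * evalue_scale`, documented as a threshold
#' device, not a biophysical claim.
#'
#' @param taxa integer vector of leaf taxids.
#' @param proportions ground-truth proportions (same length, sums to 1).
#' @param n_contigs number of contigs to simulate.
#' @param length_median,length_sigma,min_contig_len contig length model.
#' @param identity_mean,identity_sd,identity_decay percent-identity model.
#' @param off_target_rate probability of an additional hit to a relative.
#' @param bitscore_slope,bitscore_intercept,bitscore_sd bitscore model.
#' @param evalue_scale scale constant of the E-value map.
#' @param seed integer seed; all draws come from one stream.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(taxa, proportions, n_contigs,
                           length_median = 230, length_sigma = 0.5,
                           min_contig_len = 100L,
                           identity_mean = 97, identity_sd = 1,
                           identity_decay = 5, off_target_rate = 0.3,
                           bitscore_slope = 0.5, bitscore_intercept = 35,
                           bitscore_sd = 2, evalue_scale = 1e9,
                           seed = 1L) {
  stopifnot(length(taxa) == length(proportions), n_contigs > 0,
            identity_decay >= 0, off_target_rate >= 0, off_target_rate <= 1)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("ground-truth proportions must sum to 1")
  }
  structure(list(taxa = as.integer(taxa), proportions = proportions,
                 n_contigs = as.integer(n_contigs),
                 length_median = length_median,
                 length_sigma = length_sigma,
                 min_contig_len = as.integer(min_contig_len),
                 identity_mean = identity_mean, identity_sd = identity_sd,
                 identity_decay = identity_decay,
                 off_target_rate = off_target_rate,
                 bitscore_slope = bitscore_slope,
                 bitscore_intercept = bitscore_intercept,
                 bitscore_sd = bitscore_sd, evalue_scale = evalue_scale,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate a community: contigs, hit table, accession map, ground truth
#'
#' Draws contig sources and lengths per the spec, then fabricates a
#' similarity-search hit table with the statistical structure the
#' pipeline assumes: every contig has one full-length on-target hit to a
#' reference accession of its true source leaf; with probability
#' `off_target_rate` a second hit to a random relative (one or two rank
#' steps away) is emitted with rank-decayed identity and a strictly lower
#' bitscore; E-values increase monotonically as bitscores decrease.  All
#' output is deterministic for a given spec seed.
#'
#' Reference accessions are `SYN<taxid>` (unversioned in the map,
#' versioned `.1` in the hit table, exercising the version-stripping
#' fallback of [resolve_taxids()]).
#'
#' @param spec a `community_spec`.
#' @param tree the `taxonomy_tree` whose leaves the spec draws from.
#' @param dir optional output directory; writes `contigs.fasta`,
#'   `hits.tsv` (extended dialect), `acc2taxid.tsv`, `truth.json`.
#' @return list with `contigs` (named character vector of sequences),
#'   `hits` (a `hit_table`), `acc2taxid` (data.frame) and `truth`
#'   (data.frame `contig_id`, `true_taxid`, `length`, `n_ident`).
#' @export
simulate_community <- function(spec, tree, dir = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  check_taxid(tree, spec$taxa)
  n <- spec$n_contigs
  withr_seed(spec$seed, {
    src <- sample(spec$taxa, n, replace = TRUE, prob = spec$proportions)
    lens <- rlnorm_trunc(n, spec$length_median, spec$length_sigma,
                         spec$min_contig_len)
    contig_id <- sprintf("contig%06d", seq_len(n))
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- contig_id

    pid_on <- pmin(100, stats::rnorm(n, spec$identity_mean,
                                     spec$identity_sd))
    nid_on <- as.integer(floor(pid_on * lens / 100 + 0.5))
    bs_on <- spec$bitscore_slope * nid_on + spec$bitscore_intercept +
      stats::rnorm(n, 0, spec$bitscore_sd)
    rows <- list(hit_rows(contig_id, src, lens, nid_on, bs_on, spec))

    off <- stats::runif(n) < spec$off_target_rate
    if (any(off)) {
      d0 <- sample(1:2, n, replace = TRUE)  # requested rank steps
      picks <- lapply(seq_len(n), function(i)
        if (off[i]) pick_relative(tree, src[i], d0[i]) else
          c(NA_integer_, NA_integer_))
      rel <- vapply(picks, `[`, 1L, 1L)
      d <- vapply(picks, `[`, 1L, 2L)       # realised rank distance
      ok <- off & !is.na(rel)
      if (any(ok)) {
        pid_off <- pmax(50, pid_on[ok] - spec$identity_decay * d[ok])
        nid_off <- as.integer(floor(pid_off * lens[ok] / 100 + 0.5))
        bs_off <- spec$bitscore_slope * nid_off + spec$bitscore_intercept +
          stats::rnorm(sum(ok), 0, spec$bitscore_sd)
        bs_off <- pmin(bs_off, bs_on[ok] - 0.1)   # strictly below on-target
        rows[[2L]] <- hit_rows(contig_id[ok], rel[ok], lens[ok], nid_off,
                               bs_off, spec)
      }
    }
    hits <- sort_hit_table(do.call(rbind, rows))
    hits$unresolved <- NA

    acc2taxid <- data.frame(accession = paste0("SYN", spec$taxa),
                            taxid = spec$taxa, stringsAsFactors = FALSE)
    truth <- data.frame(contig_id = contig_id, true_taxid = src,
                        length = lens, n_ident = nid_on,
                        stringsAsFactors = FALSE)
    out <- list(contigs = seqs, hits = hits, acc2taxid = acc2taxid,
                truth = truth)
    if (!is.null(dir)) write_community(out, dir)
    out
  })
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

rlnorm_trunc <- function(n, median, sigma, min_len) {
  lo <- stats::plnorm(min_len, log(median), sigma)
  u <- stats::runif(n, lo, 1)
  pmax(as.integer(round(stats::qlnorm(u, log(median), sigma))),
       as.integer(min_len))
}

hit_rows <- function(qid, staxid, qlen, nident, bitscore, spec) {
  # floored far below any working threshold so E-values stay positive
  # (and comparable) at double precision even for very long contigs
  evalue <- pmax(qlen * 2^(-bitscore) * spec$evalue_scale, 1e-250)
  data.frame(qseqid = qid, sseqid = paste0("SYN", staxid, ".1"),
             pident = round(100 * nident / qlen, 2), length = qlen,
             mismatch = qlen - nident, gapopen = 0L,
             qstart = 1L, qend = qlen, sstart = 1L, send = qlen,
             evalue = evalue, bitscore = round(bitscore, 1),
             nident = nident, staxid = as.integer(staxid),
             unresolved = NA, stringsAsFactors = FALSE)
}

# a leaf whose LCA with `taxid` sits `d` rank steps above `taxid`;
# climbs further when no such relative exists (e.g. a single-species
# genus has no distance-1 relative).  Returns c(leaf, realised distance)
# or c(NA, NA).
pick_relative <- function(tree, taxid, d) {
  lin <- lineage(tree, taxid)
  while (d < length(lin)) {
    anc <- lin[length(lin) - d]
    below <- descendant_leaves(tree, anc)
    # exclude leaves under the child on taxid's own branch, so the LCA
    # with the pick is exactly `anc`
    own <- descendant_leaves(tree, lin[length(lin) - d + 1L])
    cand <- setdiff(below, own)
    if (length(cand)) {
      return(c(cand[sample.int(length(cand), 1L)], d))
    }
    d <- d + 1L
  }
  c(NA_integer_, NA_integer_)
}

descendant_leaves <- function(tree, taxid) {
  kids <- tree$nodes$taxid[tree$nodes$parent_taxid == taxid &
                             tree$nodes$taxid != taxid]
  if (length(kids) == 0L) return(taxid)
  unlist(lapply(kids, descendant_leaves, tree = tree))
}

write_community <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$contigs),
                              file.path(dir, "contigs.fasta"))
  write_hit_table(sim$hits, file.path(dir, "hits.tsv"))
  utils::write.table(sim$acc2taxid, file.path(dir, "acc2taxid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Ground-truth proportions aggregated at a rank
#'
#' @param spec a `community_spec`.
#' @param tree the taxonomy the spec lives in.
#' @param rank aggregation rank.
#' @return named numeric vector of proportions keyed by taxid at `rank`.
#' @export
truth_proportions <- function(spec, tree, rank = "family") {
  anc <- vapply(spec$taxa, function(t) ancestor_at_rank(tree, t, rank), 1L)
  p <- tapply(spec$proportions, anc, sum)
  stats::setNames(as.numeric(p), names(p))
}

#' Generate a paired two-community fixture
#'
#' Emits fixtures for two communities over a shared taxonomy, plus a
#' truth-difference table at `rank` for comparison tests: per taxon the
#' ground-truth proportion in each community and the difference (B - A).
#'
#' @param spec_a,spec_b `community_spec`s over leaves of `shared_tree`.
#' @param shared_tree the common `taxonomy_tree`.
#' @param rank rank of the truth-difference table.
#' @param dir_a,dir_b optional output directories for the fixture files.
#' @return list `a`, `b` (each as [simulate_community()]) and
#'   `truth_diff` (data.frame `taxid`, `name`, `prop_a`, `prop_b`,
#'   `diff`).
#' @export
make_paired_fixture <- function(spec_a, spec_b, shared_tree,
                                rank = "family", dir_a = NULL,
                                dir_b = NULL) {
  a <- simulate_community(spec_a, shared_tree, dir_a)
  b <- simulate_community(spec_b, shared_tree, dir_b)
  pa <- truth_proportions(spec_a, shared_tree, rank)
  pb <- truth_proportions(spec_b, shared_tree, rank)
  taxids <- sort(as.integer(union(names(pa), names(pb))))
  va <- ifelse(is.na(pa[as.character(taxids)]), 0,
               pa[as.character(taxids)])
  vb <- ifelse(is.na(pb[as.character(taxids)]), 0,
               pb[as.character(taxids)])
  truth_diff <- data.frame(taxid = taxids,
                           name = taxon_name(shared_tree, taxids),
                           prop_a = as.numeric(va), prop_b = as.numeric(vb),
                           diff = as.numeric(vb - va),
                           stringsAsFactors = FALSE)
  list(a = a, b = b, truth_diff = truth_diff)
}

#' Default paired community specs
#'
#' An 8-family, two-genera-per-family community pair emulating the
#' published contrast: community A ("p30like") is dominated by family 1
#' with family 2 second; in community B ("np30like") family 1 collapses
#' to a minor fraction while families 2 and 8 expand.  Family
#' proportions are split equally over each family's two species.
#'
#' @param n_contigs contigs per community.
#' @param seed base seed; community B uses `seed + 1`.
#' @return list with `tree`, `spec_a`, `spec_b`.
#' @export
default_paired_specs <- function(n_contigs = 5000L, seed = 1L) {
  tree <- generate_taxonomy(8L, 2L, seed)
  leaves <- attr(tree, "leaves")           # 16 species, 2 per family
  fam_a <- c(0.35, 0.20, 0.15, 0.10, 0.08, 0.05, 0.04, 0.03)
  fam_b <- c(0.10, 0.30, 0.20, 0.12, 0.10, 0.08, 0.04, 0.06)
  spread <- function(p) rep(p / 2, each = 2L)
  list(tree = tree,
       spec_a = community_spec(leaves, spread(fam_a), n_contigs,
                               seed = seed),
       spec_b = community_spec(leaves, spread(fam_b), n_contigs,
                               seed = seed + 1L))
}
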