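test_that("generate_taxonomy follows the rank skeleton deterministically", {
  # single family, single genus: a 7-node chain through all ranks
  tr <- generate_taxonomy(1L, 1L)
  expect_equal(nrow(tr$nodes), 7L)
  leaf <- attr(tr, "leaves")
  expect_length(leaf, 1L)
  lin <- lineage(tr, leaf)
  expect_length(lin, 7L)
  expect_equal(tr$nodes$rank[match(lin, tr$nodes$taxid)],
               c("no rank", "superkingdom", "class", "order", "family",
                 "genus", "species"))

  # construction arithmetic: root + superkingdom + 2 classes +
  # per family (order + family + g genera + g species)
  tr2 <- generate_taxonomy(3L, 2L)
  expect_equal(nrow(tr2$nodes), 2L + 2L + 3L * (1L + 1L + 2L + 2L))
  expect_equal(sum(tr2$nodes$rank == "family"), 3L)
  expect_equal(sum(tr2$nodes$rank == "genus"), 6L)
  expect_equal(sum(tr2$nodes$rank == "species"), 6L)
  expect_length(attr(tr2, "leaves"), 6L)

  # emitted dumps are byte-identical across runs and re-parse equal
  d1 <- tempfile(); d2 <- tempfile()
  generate_taxonomy(3L, 2L, dir = d1)
  generate_taxonomy(3L, 2L, dir = d2)
  expect_identical(readLines(file.path(d1, "nodes.dmp")),
                   readLines(file.path(d2, "nodes.dmp")))
  expect_identical(readLines(file.path(d1, "names.dmp")),
                   readLines(file.path(d2, "names.dmp")))
  tr3 <- parse_taxonomy(file.path(d1, "nodes.dmp"),
                        file.path(d1, "names.dmp"))
  expect_equal(tr3$nodes, tr2$nodes)
})

test_that("community_spec validates its ground truth", {
  tr <- generate_taxonomy(2L, 1L)
  leaves <- attr(tr, "leaves")
  expect_error(community_spec(leaves, c(0.5, 0.4), 100), "sum to 1")
  sp <- community_spec(leaves, c(0.5, 0.5), 100)
  expect_s3_class(sp, "community_spec")
})

test_that("simulate_community output parses cleanly and honours the
           hit-structure contracts", {
  tr <- generate_taxonomy(4L, 2L)
  leaves <- attr(tr, "leaves")
  sp <- community_spec(leaves, rep(1 / 8, 8), 300, seed = 5)
  sim <- simulate_community(sp, tr)

  expect_length(sim$contigs, 300L)
  expect_true(all(nchar(sim$contigs) >= 100))
  expect_true(all(nchar(sim$contigs) == sim$truth$length))
  expect_setequal(unique(sim$truth$true_taxid), leaves)

  # on-target hit outranks any off-target hit of the same contig
  best <- tapply(seq_len(nrow(sim$hits)), sim$hits$qseqid, function(ix) {
    h <- sim$hits[ix, ]
    h$staxid[which.max(h$bitscore)]
  })
  truth <- setNames(sim$truth$true_taxid, sim$truth$contig_id)
  expect_equal(as.vector(best[names(truth)]), unname(truth))

  # E-values increase as bitscores decrease within each contig
  for (q in unique(sim$hits$qseqid)[1:20]) {
    h <- sim$hits[sim$hits$qseqid == q, ]
    expect_true(all(diff(h$bitscore) <= 0))
    expect_true(all(diff(h$evalue) >= 0))
  }

  # files round-trip through the package's own readers
  d <- tempfile()
  sim2 <- simulate_community(sp, tr, dir = d)
  hits <- read_hit_table(file.path(d, "hits.tsv"))
  expect_equal(nrow(hits), nrow(sim$hits))
  fa <- Biostrings::readDNAStringSet(file.path(d, "contigs.fasta"))
  expect_equal(length(fa), 300L)
  map <- read_acc2taxid(file.path(d, "acc2taxid.tsv"))
  expect_setequal(map$taxid, leaves)
})

test_that("off_target_rate 0 gives one hit per contig and perfect UBH
           recovery", {
  tr <- generate_taxonomy(3L, 2L)
  leaves <- attr(tr, "leaves")
  sp <- community_spec(leaves, rep(1 / 6, 6), 200, off_target_rate = 0,
                       seed = 8)
  sim <- simulate_community(sp, tr)
  expect_equal(nrow(sim$hits), 200L)
  tab <- filter_hits(resolve_taxids(sim$hits, sim$acc2taxid, tr), 1e-10)
  asg <- assign_contigs(tab, tr, "ubh")
  got <- asg$taxid[match(sim$truth$contig_id, asg$contig_id)]
  expect_equal(got, sim$truth$true_taxid)
})

test_that("same seed reproduces a community byte-for-byte", {
  tr <- generate_taxonomy(3L, 2L)
  sp <- community_spec(attr(tr, "leaves"), rep(1 / 6, 6), 150, seed = 3)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_community(sp, tr, dir = d1)
  simulate_community(sp, tr, dir = d2)
  for (f in c("hits.tsv", "acc2taxid.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_identical(readBin(file.path(d1, "contigs.fasta"), "raw", 1e6),
                   readBin(file.path(d2, "contigs.fasta"), "raw", 1e6))
})

test_that("empirical draw proportions stay inside exact binomial bounds", {
  tr <- generate_taxonomy(8L, 2L)
  leaves <- attr(tr, "leaves")
  fam <- c(0.35, 0.20, 0.15, 0.10, 0.08, 0.05, 0.04, 0.03)
  sp <- community_spec(leaves, rep(fam / 2, each = 2), 5000, seed = 4)
  sim <- simulate_community(sp, tr)
  famof <- vapply(sim$truth$true_taxid, function(t)
    ancestor_at_rank(tr, t, "family"), 1L)
  counts <- table(factor(famof,
                         levels = vapply(leaves[seq(1, 16, 2)],
                                         function(t)
                                           ancestor_at_rank(tr, t,
                                                            "family"),
                                         1L)))
  for (k in seq_along(fam)) {
    ci <- stats::qbinom(c(0.005, 0.995), 5000, fam[k])
    expect_gte(counts[[k]], ci[1])
    expect_lte(counts[[k]], ci[2])
  }
})

test_that("make_paired_fixture reports the engineered contrast", {
  specs <- default_paired_specs(n_contigs = 50, seed = 6)
  fix <- make_paired_fixture(specs$spec_a, specs$spec_b, specs$tree)
  td <- fix$truth_diff
  expect_equal(sum(td$prop_a), 1, tolerance = 1e-9)
  expect_equal(sum(td$prop_b), 1, tolerance = 1e-9)
  # the dominant family of A is the one that collapses most in B
  expect_equal(td$taxid[which.min(td$diff)],
               td$taxid[which.max(td$prop_a)])

  # a family zeroed in B carries diff == -prop_a
  trB <- generate_taxonomy(2L, 1L)
  lv <- attr(trB, "leaves")
  a <- community_spec(lv, c(0.6, 0.4), 30, seed = 1)
  b <- community_spec(lv, c(0, 1), 30, seed = 2)
  fx <- make_paired_fixture(a, b, trB)
  gone <- fx$truth_diff[fx$truth_diff$prop_b == 0, ]
  expect_equal(gone$diff, -gone$prop_a)

  # identical specs -> truth difference identically zero
  fx0 <- make_paired_fixture(a, a, trB)
  expect_true(all(fx0$truth_diff$diff == 0))
})

test_that("raising off_target_rate never improves UBH leaf accuracy", {
  tr <- generate_taxonomy(4L, 2L)
  leaves <- attr(tr, "leaves")
  acc_at <- function(rate) {
    sp <- community_spec(leaves, rep(1 / 8, 8), 400,
                         off_target_rate = rate, bitscore_sd = 0,
                         identity_sd = 0, seed = 12)
    sim <- simulate_community(sp, tr)
    tab <- filter_hits(resolve_taxids(sim$hits, sim$acc2taxid, tr),
                       1e-10)
    asg <- assign_contigs(tab, tr, "ubh")
    mean(asg$taxid[match(sim$truth$contig_id, asg$contig_id)] ==
           sim$truth$true_taxid)
  }
  accs <- vapply(c(0, 0.5, 1), acc_at, 1)
  expect_true(all(diff(accs) <= 0))
})
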