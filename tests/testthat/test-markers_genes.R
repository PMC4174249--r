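rrna_table <- function(lines, tree) {
  tab <- read_hit_table(lines)
  tab$unresolved <- is.na(tab$staxid)
  tab
}

test_that("extract_rrna_contigs skips excluded names and applies the
           rRNA threshold strictly", {
  # add an 'uncultured' taxon to the toy tree
  tr <- parse_taxonomy(
    c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tsuperkingdom\t|",
      "3\t|\t2\t|\tgenus\t|", "4\t|\t2\t|\tgenus\t|"),
    c("1\t|\troot\t|\t\t|\tscientific name\t|",
      "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
      "3\t|\tuncultured bacterium\t|\t\t|\tscientific name\t|",
      "4\t|\tRoseovarius sp.\t|\t\t|\tscientific name\t|"))
  cfg <- pipeline_config()
  # best hit uncultured, second best a named organism -> second wins
  tab <- rrna_table(c(
    hit_line("c1", "U1.1", bitscore = 300, evalue = 1e-40, nident = 99,
             staxid = 3),
    hit_line("c1", "R1.1", bitscore = 250, evalue = 1e-30, nident = 95,
             staxid = 4)), tr)
  rec <- extract_rrna_contigs(tab, tr, cfg)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$best_taxid, 4L)
  expect_equal(rec$best_subject, "R1.1")
  expect_equal(rec$best_name, "Roseovarius sp.")

  # all hits excluded -> contig absent
  tab2 <- rrna_table(hit_line("c2", "U1.1", staxid = 3, nident = 99), tr)
  expect_equal(nrow(extract_rrna_contigs(tab2, tr, cfg)), 0L)

  # E-value 1e-4 fails the strict < 1e-5 rRNA threshold
  tab3 <- rrna_table(hit_line("c3", "R1.1", evalue = 1e-4, staxid = 4,
                              nident = 99), tr)
  expect_equal(nrow(extract_rrna_contigs(tab3, tr, cfg)), 0L)

  # chimeric contigs are dropped regardless of hits
  tab4 <- rrna_table(hit_line("c4", "R1.1", staxid = 4, nident = 99), tr)
  expect_equal(nrow(extract_rrna_contigs(tab4, tr, cfg,
                                         c(c4 = TRUE))), 0L)
  expect_equal(nrow(extract_rrna_contigs(tab4, tr, cfg,
                                         c(c4 = FALSE))), 1L)
})

test_that("load_gene_map keys versioned and unversioned accessions", {
  g2a <- c("#tax_id\tGeneID\tstatus\taccession",
           "99\tG1\t-\tNC_0001.2",
           "99\tG1\t-\tAB1234.1",      # two accessions, one gene
           "99\tG2\t-\t-",             # placeholder accession: skipped
           "99\tG3\t-\tXY9999.1")      # GeneID missing from gene_info
  gi <- c("#tax_id\tGeneID\tSymbol",
          "99\tG1\tpcrA",
          "99\tG2\tcld")
  map <- load_gene_map(g2a, gi)
  expect_equal(map$symbol[map$accession == "NC_0001.2"], "pcrA")
  expect_equal(map$symbol[map$accession == "NC_0001"], "pcrA")
  expect_equal(map$symbol[map$accession == "AB1234.1"], "pcrA")
  expect_false("-" %in% map$accession)
  expect_equal(map$symbol[map$accession == "XY9999.1"], "")
  expect_equal(attr(map, "n_missing_symbol"), 1L)
})

test_that("annotate_genes picks the best cataloged hit per category", {
  catalog <- read_gene_catalog()
  tab <- read_hit_table(c(
    hit_line("c1", "CLD001.1", bitscore = 90, nident = 80, staxid = 5),
    hit_line("c1", "NARG001.1", bitscore = 80, nident = 70, staxid = 5),
    hit_line("c1", "PCRA001.1", bitscore = 95, nident = 85, staxid = 5),
    hit_line("c2", "ZZZZ.1", bitscore = 99, nident = 90, staxid = 5)))
  ann <- annotate_genes(tab, NULL, catalog)
  expect_equal(sort(ann$gene_symbol[ann$contig_id == "c1"]),
               c("cld", "narG", "pcrA"))
  expect_false("c2" %in% ann$contig_id)   # no cataloged subject
  # one annotation per contig per category, best hit wins
  expect_equal(ann$gene_symbol[ann$contig_id == "c1" &
                                 ann$category == "perchlorate reduction"],
               "pcrA")
  # idempotent: annotating the annotated contigs again changes nothing
  again <- annotate_genes(tab[tab$qseqid %in% ann$contig_id, ], NULL,
                          catalog)
  expect_equal(again, ann)

  # resolution through a gene map for uncataloged accessions
  gmap <- load_gene_map(c("9\tG7\t-\tMAPPED01.1"), c("9\tG7\tnarH"))
  tab2 <- read_hit_table(hit_line("c3", "MAPPED01.1", nident = 88,
                                  staxid = 5))
  ann2 <- annotate_genes(tab2, gmap, catalog)
  expect_equal(ann2$gene_symbol, "narH")
  expect_equal(ann2$category, "nitrate reduction")
})

test_that("tabulate_gene_taxonomy counts groups with an Undefined row", {
  tr <- toy_tree()
  # two contigs assigned under class 3, one unassigned
  asg <- make_assignments(c("c1", "c2", "c3"), c(5L, 8L, NA),
                          c(90L, 80L, 0L))
  ann <- data.frame(contig_id = c("c1", "c2", "c3"),
                    gene_symbol = "narG", category = "nitrate reduction",
                    subject_accession = "NARG001.1", bitscore = 90,
                    evalue = 1e-30, source = "blastn",
                    stringsAsFactors = FALSE)
  tb <- tabulate_gene_taxonomy(ann, asg, tr, "class", "nitrate reduction")
  expect_equal(tb$blastn[tb$group == "Proteobacteria"], 2L)
  expect_equal(tb$blastn[tb$group == "Undefined"], 1L)
  expect_equal(tb$blastn[tb$group == "Total"], 3L)

  # empty annotations give a zero-total table
  tb0 <- tabulate_gene_taxonomy(ann[0, ], asg, tr, "class",
                                "nitrate reduction")
  expect_equal(tb0[[2]][tb0$group == "Total"], 0L)

  # totals row equals column sums on fuzzed inputs, and Undefined absorbs
  # exactly the rank-unresolved contigs
  set.seed(17)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    ids <- sprintf("f%03d", seq_len(n))
    tax <- sample(c(tr$nodes$taxid, NA), n, replace = TRUE)
    asg <- make_assignments(ids, tax, ifelse(is.na(tax), 0L, 50L))
    ann <- data.frame(contig_id = ids, gene_symbol = "narG",
                      category = "nitrate reduction",
                      subject_accession = "x", bitscore = 1, evalue = 0,
                      source = sample(c("blastn", "blastx"), n,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
    tb <- tabulate_gene_taxonomy(ann, asg, tr, "class",
                                 "nitrate reduction")
    body <- tb[tb$group != "Total", -1, drop = FALSE]
    expect_equal(unname(unlist(tb[tb$group == "Total", -1])),
                 unname(colSums(body)))
    # contigs whose assignment has no class ancestor land in Undefined
    undef_expected <- sum(vapply(seq_len(n), function(k) {
      if (is.na(tax[k])) return(TRUE)
      is.na(ancestor_at_rank(tr, tax[k], "class"))
    }, TRUE))
    expect_equal(sum(unlist(tb[tb$group == "Undefined", -1])),
                 undef_expected)
  }
})
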