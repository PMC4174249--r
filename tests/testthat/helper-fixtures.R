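# Shared fixtures, built in code.

# root -> Bacteria -> Proteobacteria -> Rhodocyclaceae -> {Azoarcus, Thauera}
# plus a sibling family Rhodobacteraceae -> Roseovarius
toy_tree <- function() {
  nodes <- c("1\t|\t1\t|\tno rank\t|",
             "2\t|\t1\t|\tsuperkingdom\t|",
             "3\t|\t2\t|\tclass\t|",
             "4\t|\t3\t|\tfamily\t|",
             "5\t|\t4\t|\tgenus\t|",
             "6\t|\t4\t|\tgenus\t|",
             "7\t|\t3\t|\tfamily\t|",
             "8\t|\t7\t|\tgenus\t|")
  names <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
             "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
             "3\t|\tProteobacteria\t|\t\t|\tscientific name\t|",
             "4\t|\tRhodocyclaceae\t|\t\t|\tscientific name\t|",
             "5\t|\tAzoarcus\t|\t\t|\tscientific name\t|",
             "6\t|\tThauera\t|\t\t|\tscientific name\t|",
             "7\t|\tRhodobacteraceae\t|\t\t|\tscientific name\t|",
             "8\t|\tRoseovarius\t|\t\t|\tscientific name\t|")
  parse_taxonomy(nodes, names)
}

# random rooted tree over n nodes: parent of node k drawn from 1..k-1
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(1L, vapply(2:n, function(k) sample.int(k - 1L, 1L), 1L))
  ranks <- sample(c("class", "order", "family", "genus", "species",
                    "no rank"), n, replace = TRUE)
  df <- data.frame(taxid = seq_len(n), parent_taxid = parent,
                   rank = ranks,
                   scientific_name = sprintf("taxon%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", df$taxid, df$parent_taxid,
                   df$rank)
  names <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", df$taxid,
                   df$scientific_name)
  parse_taxonomy(nodes, names)
}

# one tabular hit line in the 12- or 14-column dialect
hit_line <- function(qseqid, sseqid, pident = NULL, length = 100,
                     evalue = 1e-30, bitscore = 200, nident = NULL,
                     staxid = NULL) {
  if (is.null(pident)) {
    pident <- if (is.null(nident)) 99 else round(100 * nident / length, 2)
  }
  base <- paste(qseqid, sseqid, pident, length,
                length - round(pident * length / 100), 0, 1, length, 1,
                length, format(evalue, scientific = TRUE), bitscore,
                sep = "\t")
  if (is.null(nident)) return(base)
  paste(base, nident, staxid, sep = "\t")
}

# random extended-dialect hit table as parsed lines
random_hit_lines <- function(n, seed, n_queries = max(1L, n %/% 5L)) {
  set.seed(seed)
  len <- sample(100:500, n, replace = TRUE)
  nid <- round(len * runif(n, 0.6, 1))
  vapply(seq_len(n), function(i) {
    hit_line(sprintf("q%03d", sample.int(n_queries, 1L)),
             sprintf("ACC%04d.%d", sample.int(2000, 1L),
                     sample.int(3, 1L)),
             pident = round(100 * nid[i] / len[i], 2), length = len[i],
             evalue = 10^runif(1, -50, -2),
             bitscore = round(runif(1, 40, 400), 1), nident = nid[i],
             staxid = sample.int(8, 1L))
  }, "")
}

make_assignments <- function(contig_id, taxid, weight, method = "UBH") {
  df <- data.frame(contig_id = contig_id, taxid = as.integer(taxid),
                   method = method, weight = as.integer(weight),
                   n_evidence = ifelse(is.na(taxid), 0L, 1L),
                   stringsAsFactors = FALSE)
  df$evidence <- lapply(seq_len(nrow(df)), function(i)
    if (is.na(df$taxid[i])) character(0) else "ev")
  df
}
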