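#' Run the full contig annotation pipeline on one community
#'
#' Wires the stages together: read contigs and hit files, resolve subject
#' taxids, apply the per-database-class E-value threshold
#' (`evalue_max_global` for nt/nr-class files, `evalue_max_rrna` for
#' rRNA-class files), bin contigs by UBH and LCA, build identity-weighted
#' abundance profiles at the report and group ranks, select the
#' cumulative-fraction top families, compute assembly statistics, catalog
#' rRNA markers and annotate cataloged functional genes, then write
#' everything to `out_dir` under fixed file names
#' (`profile_<rank>_<method>.tsv`, `top_families.tsv`,
#' `contig_stats.tsv`, `markers.tsv`, `genes_<category>.tsv`,
#' `manifest.json`).
#'
#' @param contigs path to a contig FASTA file.
#' @param hit_files named character vector of hit-table paths; names give
#'   each file's database class, `"global"` (nt/nr-like) or `"rrna"`.
#' @param taxonomy_dir directory holding `nodes.dmp` and `names.dmp`.
#' @param acc2taxid path to the accession-to-taxid TSV.
#' @param out_dir output directory (created).
#' @param config a `pipeline_config` or a YAML path.
#' @param gene_catalog optional gene catalog TSV path; when given,
#'   gene-taxon tables are produced for each catalog category.
#' @param gene_map optional list(gene2accession=, gene_info=) paths.
#' @param chimera_flags optional two-column TSV (contig_id, Y/N) marking
#'   chimeric contigs.
#' @return Invisibly, the run manifest (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(contigs, hit_files, taxonomy_dir, acc2taxid,
                         out_dir, config = pipeline_config(),
                         gene_catalog = NULL, gene_map = NULL,
                         chimera_flags = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- Sys.time()
  for (f in c(contigs, unname(hit_files), acc2taxid,
              file.path(taxonomy_dir, c("nodes.dmp", "names.dmp")))) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  if (is.null(names(hit_files)) || !all(names(hit_files) %in%
                                        c("global", "rrna"))) {
    stop("hit_files must be named with database classes 'global'/'rrna'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tree <- parse_taxonomy(file.path(taxonomy_dir, "nodes.dmp"),
                         file.path(taxonomy_dir, "names.dmp"))
  seqs <- Biostrings::readDNAStringSet(contigs)
  contig_ids <- sub("\\s.*", "", names(seqs))
  map <- read_acc2taxid(acc2taxid)

  stats <- contig_stats(Biostrings::width(seqs), config$min_contig_len)
  write_contig_stats(stats, file.path(out_dir, "contig_stats.tsv"))

  flags <- NULL
  if (!is.null(chimera_flags)) {
    fl <- utils::read.table(chimera_flags, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("contig_id", "flag"))
    flags <- stats::setNames(toupper(fl$flag) == "Y", fl$contig_id)
  }

  n_read <- 0L
  n_kept <- 0L
  global_tabs <- list()
  markers <- NULL
  for (i in seq_along(hit_files)) {
    tab <- read_hit_table(hit_files[i])
    n_read <- n_read + nrow(tab)
    tab <- resolve_taxids(tab, map, tree)
    if (names(hit_files)[i] == "rrna") {
      mk <- extract_rrna_contigs(tab, tree, config, flags)
      markers <- if (is.null(markers)) mk else rbind(markers, mk)
      n_kept <- n_kept + nrow(filter_hits(tab, config$evalue_max_rrna))
    } else {
      tab <- filter_hits(tab, config$evalue_max_global)
      n_kept <- n_kept + nrow(tab)
      global_tabs[[length(global_tabs) + 1L]] <- tab
    }
  }
  gtab <- if (length(global_tabs)) {
    sort_hit_table(do.call(rbind, global_tabs))
  } else {
    empty_hit_table()
  }

  assignments <- list()
  profiles <- list()
  for (method in c("ubh", "lca")) {
    asg <- assign_contigs(gtab, tree, method,
                          top_percent = config$lca_top_percent,
                          contig_ids = contig_ids)
    assignments[[method]] <- asg
    for (rank in unique(c(config$report_rank, config$group_rank))) {
      prof <- compute_profile(asg, tree, rank)
      profiles[[paste(rank, method, sep = "_")]] <- prof
      write_profile_tsv(prof,
                        file.path(out_dir,
                                  sprintf("profile_%s_%s.tsv", rank, method)),
                        tree, config$group_rank)
    }
  }

  top_prof <- profiles[[paste(config$report_rank, "ubh", sep = "_")]]
  top <- cumulative_select(top_prof, config$cumulative_frac)
  utils::write.table(
    data.frame(taxid = top, name = taxon_name(tree, top)),
    file.path(out_dir, "top_families.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(markers)) {
    utils::write.table(markers, file.path(out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(gene_catalog)) {
    catalog <- read_gene_catalog(gene_catalog)
    gmap <- NULL
    if (!is.null(gene_map)) {
      gmap <- load_gene_map(gene_map$gene2accession, gene_map$gene_info)
    }
    ann <- annotate_genes(gtab, gmap, catalog)
    for (category in unique(catalog$category)) {
      tb <- tabulate_gene_taxonomy(ann, assignments$ubh, tree,
                                   config$group_rank, category)
      utils::write.table(tb,
                         file.path(out_dir,
                                   sprintf("genes_%s.tsv",
                                           gsub("\\s+", "_", category))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(c(contigs, unname(hit_files),
                                     acc2taxid))),
    counts = list(
      contigs_in = length(seqs),
      hits_read = n_read,
      hits_retained = n_kept,
      contigs_assigned_ubh = sum(!is.na(assignments$ubh$taxid)),
      contigs_assigned_lca = sum(!is.na(assignments$lca$taxid)),
      taxa_reported = nrow(top_prof$entries),
      markers = if (is.null(markers)) 0L else nrow(markers)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_contig_stats <- function(stats, path) {
  df <- data.frame(statistic = c("n_contigs", "total_nt", "longest",
                                 "shortest", "mean", "n50"),
                   value = c(stats$n_contigs, stats$total_nt,
                             stats$longest, stats$shortest,
                             round(stats$mean, 2), stats$n50))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare the profiles of two pipeline output directories
#'
#' Reads the same-rank, same-method profile TSVs from two [run_pipeline()]
#' output directories and writes their comparison table (see
#' [compare_profiles()]) under the chosen ordering.
#'
#' @param dir_a,dir_b pipeline output directories.
#' @param rank,method which profile to compare.
#' @param ordering `"by_mean"` or `"by_class"`.
#' @param out output TSV path (default `comparison.tsv` beside `dir_a`'s
#'   parent); `NULL` to skip writing.
#' @return The comparison data.frame.
#' @export
compare_command <- function(dir_a, dir_b, rank = "family",
                            method = "ubh",
                            ordering = c("by_mean", "by_class"),
                            out = NULL) {
  ordering <- match.arg(ordering)
  fa <- file.path(dir_a, sprintf("profile_%s_%s.tsv", rank, method))
  fb <- file.path(dir_b, sprintf("profile_%s_%s.tsv", rank, method))
  for (f in c(fa, fb)) if (!file.exists(f)) stop("missing profile: ", f)
  pa <- read_profile_tsv(fa)
  pb <- read_profile_tsv(fb)
  if (!is.na(pa$rank) && !is.na(pb$rank) &&
      !identical(pa$rank, pb$rank)) {
    stop("profiles are at different ranks")
  }
  cmp <- compare_profiles(pa, pb, tree = NULL, ordering = "by_mean")
  # class grouping comes from the class_name column the profile TSVs carry
  cls_a <- stats::setNames(pa$class_name, pa$entries$taxid)
  cls_b <- stats::setNames(pb$class_name, pb$entries$taxid)
  cls <- cls_a[as.character(cmp$taxid)]
  cls[is.na(cls)] <- cls_b[as.character(cmp$taxid)][is.na(cls)]
  cmp$class_name <- unname(cls)
  if (ordering == "by_class") {
    csum <- tapply(cmp$mean, cmp$class_name, sum)
    key <- -as.numeric(csum[cmp$class_name])
    key[is.na(key)] <- Inf
    cmp <- cmp[order(key, cmp$class_name, -cmp$mean, cmp$taxid), ,
               drop = FALSE]
    rownames(cmp) <- NULL
  }
  if (!is.null(out)) {
    utils::write.table(cmp, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cmp
}
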