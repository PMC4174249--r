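Package: contigtax
Title: Taxonomic Binning and Identity-Weighted Abundance Profiling of
    Metagenomic Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly comparative annotation of metagenomic contigs from
    tabular similarity-search results. Parses NCBI-style taxonomy dumps into a
    rooted tree with lineage, rank and lowest-common-ancestor queries; reads,
    E-value-filters and taxid-resolves BLAST-style 12-column hit tables; bins
    contigs by unique best hit (UBH) or lowest common ancestor (LCA); builds
    identity-weighted relative-abundance profiles at any rank with
    cumulative-fraction family selection and two-community comparison; catalogs
    rRNA marker contigs under a best-hit rule that excludes uncultured and
    unidentified subjects; annotates functional genes through
    gene2accession/gene_info maps and tabulates them by taxonomic group;
    computes assembly statistics (N50 and friends); and ships a deterministic
    synthetic-community generator so every stage is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
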