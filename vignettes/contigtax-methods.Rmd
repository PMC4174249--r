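---
title: "contigtax: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{contigtax: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigtax)
```

## The problem

A shotgun metagenome of a mixed microbial culture is assembled into
contigs, the contigs are searched against reference databases, and the
community's taxonomic composition is reconstructed from the resulting
hit tables.  `contigtax` implements this post-assembly stage for
comparative two-community designs — for instance an anaerobic
perchlorate-reducing enrichment culture profiled with and without an
added electron acceptor, where the interesting result is which bacterial
families expand or collapse between the two conditions.

The package deliberately consumes the outputs of external tools
(assembler contigs, tabular BLAST/BLAT hits, chimera-screen flags) and
produces tables; running the searches, assembling reads and detecting
chimeras are out of scope.

## Taxonomic binning

Each contig's hits are first resolved to taxids (exact accession match,
then with the `.N` version suffix stripped) and filtered at the E-value
threshold of the database class they came from: strictly below `1e-10`
for comprehensive nucleotide/protein databases and strictly below
`1e-5` for rRNA databases.  The inequality is strict on purpose: a hit
at exactly the threshold is discarded.

Two assignment rules are provided.

* **UBH (Unique Best Hit).** The highest-bitscore stratum containing at
  least one taxid-resolved hit decides the call; a unique top hit
  assigns its subject's taxon, several hits tied at the top bitscore
  assign the lowest common ancestor (LCA) of their taxa.  Strata whose
  hits are all unresolved are skipped rather than blocking the call.
* **LCA.** All resolved hits whose bitscore is at least
  `(1 - top_percent/100)` of the contig's best resolved bitscore form
  the candidate set, and the call is the LCA of their taxa.  The default
  window of 10% follows common practice for LCA-based metagenome
  classifiers; with a window of zero and a unique best hit the rule
  reduces exactly to UBH, which the test suite asserts.

Both rules re-sort the hits internally (bitscore descending, E-value
ascending, then subject accession), so assignments are invariant to the
order hits arrive in.  The accession tie-break is a convention chosen
for determinism; nothing in the method depends on it.

## Identity-weighted abundance

The abundance statistic is built on identity counts: the number of
alignment columns where contig and subject agree (`nident` when the
search tool reports it, otherwise `round(pident × length / 100)` with
half-up rounding).  At a reporting rank `r` (family by default), each
assigned contig contributes one weight — the identity count of its best
hit; on ties, the maximum among tied hits — to its ancestor at `r`, and

```
proportion(t) = weight(t) / Σ_u weight(u)
```

over the taxa resolved at that rank.  Two choices here were genuinely
open:

* **One weight per contig.**  The source material defines the statistic
  as "identities in contigs assigned to a taxon" without fixing which
  hit's identities count when several hits support an LCA call.  We use
  the maximum identity count among the contributing hits, so every
  contig is counted exactly once; summing across hits would let
  multi-hit contigs dominate.  A per-hit-sum variant was considered and
  rejected as double counting.
* **Denominator excludes rank-unresolved weight.**  Contigs that are
  unassigned, or assigned above the reporting rank, accumulate into
  `unassigned_weight`, which is reported alongside the profile but kept
  out of the proportion denominator — proportions describe the
  composition of what *was* resolved at the rank.

Displays keep the most abundant families up to a cumulative proportion
(`cumulative_frac`, default 0.90); the selection is the shortest
descending-abundance prefix reaching the cutoff, with ascending-taxid
tie-break for determinism.  Two-community comparisons take the union of
taxa, treat absence as zero, and order either by mean proportion or
grouped by class (classes ordered by their summed mean), mirroring the
two standard presentations of such data.

## Assembly statistics

`contig_stats()` reports count, total nucleotides, longest, shortest,
mean and N50 over contigs of length **≥ 100 nt**.  The floor is
inclusive even though such tables are often labelled "> 100 nt": the
assembler's minimum contig size is 100 and reported shortest sequences
equal 100, so the inclusive reading is the only self-consistent one.
N50 is the largest length L such that contigs of length ≥ L contain at
least half of the retained bases; the implementation is checked against
a brute-force scan over all candidate lengths.

## Marker genes and functional genes

16S rRNA contigs are cataloged by best hit after dropping externally
flagged chimeras and skipping subjects whose scientific name contains an
exclusion term.  The source material names only "uncultured or
unidentified" organisms; the shipped default vocabulary —
`uncultured`, `unidentified`, `environmental sample`, `metagenome` —
extends this to the common NCBI placeholder names and is fully
configurable (`exclusion_terms` in `pipeline_config()`).

Functional annotation walks each contig's hits best-first and accepts
the first hit whose subject is either a member accession of the editable
gene catalog (`inst/extdata/gene_catalog.tsv`; shipped accessions are
synthetic placeholders) or maps through `gene2accession`/`gene_info` to
a cataloged symbol.  One annotation per contig per category keeps the
tabulation idempotent.  Gene–taxon tables count contigs per taxonomic
group at `group_rank` with an `Undefined` row absorbing unassigned or
rank-unresolved contigs; columns are independent tallies per annotation
source, since per-source totals in such tables generally differ.

## Global percent identity

`global_percent_identity()` is a Needleman–Wunsch global aligner with
linear gap costs (defaults: match +1, mismatch −1, gap −2; a
substitution matrix may replace match/mismatch for proteins), returning
`100 × identical columns / alignment columns`.  Ties during traceback
are resolved deterministically — diagonal, then up, then left — and the
test suite verifies both the score and the tie-broken identity against
exhaustive enumeration of every global alignment for short pairs, plus
the score against an independent aligner.  The published percent
identities for recovered gene subunits came from unspecified alignment
tools and parameters; this function makes no claim of matching them, it
provides a reproducible in-package equivalent.

## The synthetic-community generator

`generate_taxonomy()` builds a fixed rank skeleton (root → superkingdom
→ class → order → family → genus → species) with one order per family,
families round-robin over two classes, and `simulate_community()` draws
contigs from a ground-truth leaf-proportion vector.  Defaults emulate
the short-contig regime of 36-mer-read assemblies:

* lengths log-normal, median 230 nt, log-sd 0.5, truncated at 100 nt
  (matching mean contig lengths of roughly 180–230 nt and N50 of
  ~180–260 nt in that regime);
* on-target percent identity Gaussian around 97 (sd 1), losing 5
  percentage points per taxonomic rank step for off-target hits;
* with probability 0.3 a contig also hits a relative one or two rank
  steps away (climbing further when the tree has no relative at the
  requested distance);
* bitscores affine in the identity count (slope 0.5, intercept 35,
  Gaussian noise sd 2), with off-target bitscores clamped at least 0.1
  bit below the on-target hit — the generator guarantees the best hit is
  always the true source, so off-target hits perturb LCA calls (they
  fall inside the 10% window) but never UBH calls;
* E-values via the strictly monotone map `E = qlen · 2^(−bitscore) ·
  10^9`, floored at `1e-250` so values remain positive and comparable in
  double precision.  The map is a threshold device, not a biophysical
  model.  The affine coefficients were chosen so that default-length
  contigs produce E-values around `1e-15`–`1e-30`: comfortably below the
  `1e-10` working threshold yet far from the floor.

The default paired fixture contrasts a community dominated by family 1
(35%) with one where that family collapses to 10% while families 2 and
8 expand — the qualitative pattern of a dominant family disappearing
under a changed electron-acceptor regime.

What the generator does **not** emulate: real sequence composition
(contigs are uniform random nucleotides), sequencing error and coverage
structure, assembly artifacts and chimeras, database incompleteness, and
conserved-region cross-mapping.  Passing recovery tests therefore shows
the *pipeline arithmetic* is correct under the stated noise model, not
that any particular real community would be recovered this accurately.

## Numerical and degenerate-input choices

* All thresholds are strict inequalities; filtering is idempotent and
  composes as the minimum of thresholds.
* Identity-count recovery rounds half-up (`floor(x + 0.5)`), never
  exceeding the alignment length.
* Profiles over an empty assigned set are valid objects with zero
  entries; `cumulative_select` on them returns an empty vector; contig
  statistics over an empty retained set are an error (there is no
  meaningful N50 of nothing).
* A taxid appearing together with the root yields the root as LCA — a
  depth-0 answer, never an error.  Merged/deleted taxid histories are
  not consumed; unknown taxids are hard errors.
* One seed drives each simulation through a single RNG stream, and the
  generator restores the caller's RNG state, so fixtures are
  byte-reproducible and independent of surrounding code.

## Problem sizes and runtime

The test suite works at deliberately small scale: toy trees of 8–200
nodes, hit tables of ≤ 500 rows, communities of 200–5,000 contigs, and
alignment oracle pairs of length ≤ 8 (exhaustive enumeration grows
combinatorially beyond that).  Composition-recovery checks use 200 /
1,000 / 5,000 contigs with a fixed seed; at 5,000 contigs the family-
profile L1 error is ≈ 0.02–0.04, consistent with multinomial sampling
noise under identity weighting, and it shrinks as contig count grows.

## Known limitations

* UBH accuracy on synthetic data is perfect by construction (the
  on-target hit always scores highest), so recovery error measures
  sampling noise, not classifier confusion; real communities with
  database gaps will behave worse.
* Rank strings are compared literally (lowercased, trimmed) with no
  synonym table; taxonomies using non-standard rank vocabularies must be
  normalised upstream.
* The aligner is quadratic time and memory; it is intended for gene- and
  subunit-scale comparisons, not genome alignment.
* E-values below `1e-250` are indistinguishable in the generator's
  output; at default parameters this regime is effectively unreachable
  (contigs beyond ~7 kb).
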