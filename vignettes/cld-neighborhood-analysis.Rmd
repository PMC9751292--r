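---
title: "Anchored comparative genomics with chlorite dismutase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored comparative genomics with chlorite dismutase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldatlas)
```

# The model

`cldatlas` treats the chlorite dismutase gene *cld* as a biomarker and
asks two questions of any collection of genomes and metagenome contigs:
*which proteins are genuine Cld*, and *which other genes travel with
cld*. The package rests on two assumptions: a microorganism encoding Cld
has experienced chlorite, and genetic proximity to *cld* raises the
probability that a gene's function is related to chlorine redox biology.
Everything else is machinery for making those two statements precise and
reproducible.

## Cld identification by catalytic key residues

Public annotations of the Cld family (which also contains
coproheme-decarboxylase relatives) are unreliable, so Cld is defined
*functionally*: a family protein is Cld if and only if it retains the
four residues jointly required for chlorite:O2 lyase activity - the
proximal heme lysine, histidine, distal heme arginine and glutamate,
at positions 92, 114, 127 and 167 of the ungapped *Nitrobacter
winogradskyi* Nb-255 reference. `map_reference_residues()` converts
those ungapped positions into alignment columns by walking the aligned
reference, and `count_key_residues()` scores every protein at the mapped
columns.

Choices made here, and why:

* **Exact matching.** A key residue counts only when the amino acid is
  identical (case-insensitive). Conservative substitutions do not count:
  the discrete 0-4 residue count is the unit of the analysis and any
  looser rule would need biochemical evidence we do not have.
  Ambiguity codes (X, B, Z) and gaps never match.
* **Gaps are reported separately** (`n_key_gaps`): a metagenomic
  fragment truncated over a key column is distinguishable from a
  substitution, and downstream users can decide which convention to
  apply. The classifier itself treats both as "residue absent".
* **Terminal extensions.** The average Cld occupies a column span; the
  mean first- and last-occupied columns (arithmetic means, rounded half
  away from zero - a fixed rule where none is canonical) define that
  span, and residues strictly outside it count as N-/C-terminal
  extensions. Extensions over 20 aa are flagged; they may be gene-calling
  artifacts or genuine fusion domains, and the flag deliberately does not
  decide which.
* **Signal peptides are ingested, never predicted.** Export prediction
  is its own discipline; `cld_calls()` merges a two-column TSV from any
  external predictor.

## Clade partitioning

`partition_clades()` summarises a rooted Cld phylogeny as disjoint
clades: in pre-order from the root, the first node whose *mean*
node-to-descendant-leaf path length is within the threshold is emitted
and not descended. This yields the coarsest partition in which every
clade satisfies the bound (parent maximality), and leaves that never
meet a qualifying ancestor become singletons, so the partition always
covers the leaf set. The comparison is `<=` by default; ties at exact
equality are measure-zero on real branch lengths, and the `inclusive`
flag exposes the alternative. Multifurcations and zero-length branches
are allowed; an unrooted tree is an error, because "mean distance below
a node" is meaningless without a root - rooting is the caller's
responsibility. Clade ids are assigned by pre-order discovery rank; the
numbering is stable for a given tree but is not claimed to match any
published clade numbering, and the threshold producing any particular
published clade count is a free parameter. Per-clade summaries
(`summarize_clades()`) report residue conservation, source and length
statistics, genus counts, and whether a clade holds an identical
sequence under two genera - the most direct signal of recent horizontal
transfer.

## Neighborhoods, subfamilies and the linkage statistic

A genomic neighborhood is the anchor *cld* gene plus up to `radius`
(default 10) genes on each side on the same contig, in *ordinal* gene
coordinates (0-based index along the contig after sorting by start, end,
gene id). Offsets are strand-agnostic: no reorientation rule is applied
because none is defensible without knowing operon structure. Two nearby
anchors produce two overlapping neighborhoods; only neighborhoods with
*identical* member sets are collapsed (first anchor kept), which is why
the number of neighborhoods can be slightly below the number of anchors.

Neighborhood proteins are grouped into subfamilies either by importing a
representative-member cluster file from an external tool (the
authoritative path for reproducing published tables) or by the package's
native `greedy_cluster()`: proteins in decreasing length order join the
first subfamily whose accumulated k-mer profile contains at least half
of their 5-mers (with mutual length coverage >= 0.5), else found a new
one. Scoring against the growing member-k-mer union rather than the
founder alone keeps joins stable as within-subfamily divergence
accumulates. This clusterer is deterministic and alignment-free; it
approximates, and does not reproduce, alignment-based clustering. When
Cld calls are available the Cld lineages are pinned to the fixed ids
`cld_1`/`cld_2` so they appear as stable rows in linkage tables.

The linkage statistic is the local clustering coefficient on the
subfamily co-occurrence network: nodes are subfamilies, an unweighted
edge joins two subfamilies found together in at least one neighborhood
(a configurable minimum count defaults to 1, as no stricter filter is
canonical), self-loops are excluded, and for a node with `k` neighbors
carrying `e` edges among them `C = e / (k(k-1)/2)`, defined as 0 for
`k < 2` (the common library convention). The computation uses integer
edge counts, so the value is exact up to one final division. The logic
of the statistic: a subfamily that co-occurs with *many different*
neighborhood repertoires has neighbors that are rarely neighbors of each
other, hence a low coefficient - and recurring across unrelated contexts
is exactly what genetic linkage to the anchor looks like, as opposed to
co-location by chance. The hit rule is strict (`C < 0.1`). For the
anchor's own subfamilies the coefficient instead measures the diversity
of contexts the anchor occupies.

## Neighborhood grouping

Neighborhoods with at least 10 genes are encoded as binary subfamily
presence/absence rows (the anchor's own subfamily columns included - no
exclusion rule is stated anywhere, and they carry real signal, e.g.
lineage 1 vs 2 contexts). The matrix is reduced by PCA to 50 components
(clipped to the matrix dimensions), embedded in two dimensions with
t-SNE (perplexity 50, 5000 iterations; exact gradient by default), and
grouped with DBSCAN at radius 4 in embedding units. `min_samples` is not
stated by any source; the package defaults to the common value 5 and
records it, with every other parameter, in the result's `parameters`
attribute. Points in no dense region form the noise pseudo-group
(group 0), mirroring the catch-all group seen in practice. The
embedding is stochastic: identical seeds reproduce identical labels, but
label identities across seeds are meaningless, so all evaluation uses
the adjusted Rand index. The package asserts structure-recovery
properties on planted data only; it never claims to reproduce a
particular published group count or layout.

## Reductase screen and frequency metrics

The screen consumes HMMER `tblout`/`domtblout` tables for
DMSO-reductase-family models (the search itself is external). A genome
with Cld and no hit below the E-value cutoff is a candidate
"non-(per)chlorate reducer": its chlorite must come from something other
than enzymatic (per)chlorate reduction, e.g. oxidative chemistry. The
cutoff (default 1e-5, full-sequence E-value) is an assumption, recorded
in the output, because no published criterion exists; raising it can
only move genomes from non-reducer to potential-reducer (a tested
monotonicity).

Frequency metrics normalise biomarker counts: `cld_per_million()` is
`n_cld / n_genes * 1e6`, and `percent_genomes()` converts a per-million
rate to an estimated percent of genomes assuming 5000 genes per
bacterial genome, so 1 per million is 0.5%. Environments enter
comparisons only above a strict 10-million-gene sample size.

# The synthetic-data generator

`generate_dataset()` is first-class, tested code that emulates exactly
the data shapes the pipeline consumes: contigs of ordered genes with
planted *cld* anchors; associated subfamilies placed with configured
probability within a configured offset of each anchor; neighborhood
archetypes (disjoint subfamily repertoires that flanking genes draw
from); proteins as point-mutated copies of per-subfamily templates; Cld
proteins as copies of a fixed 250-aa Cld-like template whose key-residue
columns are controlled exactly (a planted protein loses one uniformly
chosen key residue with probability `residue_mutation_rate`); a
coalescent tree over the Cld proteins; and optionally one Cld sequence
duplicated verbatim under two genera.

Default conditions, chosen once: within-subfamily divergence 0.05
point-mutation rate (subfamily members in real clusterings are
high-identity homologs; 5% divergence is typical of such families and
exercises the clusterer non-trivially), background Cld mutation rate
0.02 outside key columns, 150-300 aa background protein lengths, a
70/30 genomic/metagenomic source split, and genus labels from a small
fixed vocabulary. Decision uniforms are drawn in fixed positions of the
random stream, so runs with the same seed and different rates are
coupled - the fraction of intact Cld is *exactly* monotone in the
mutation rate, which the suite exploits.

What the generator deliberately does **not** emulate: realistic sequence
evolution (no indels, no rate heterogeneity, no codon structure),
operonic strand structure, assembly fragmentation, or annotation noise.
Passing tests therefore demonstrate that the algorithms recover planted
structure under controlled conditions, not that real metagenomes will be
as clean; on real data the external clustering and alignment tools
remain the authoritative front end.

# Numerical choices and degenerate inputs

* Clustering coefficients from integer counts; linkage tables are sorted
  ascending with ties broken by subfamily id; hit rule strictly `<`.
* Clade means compared with `<=` (configurable); mean span columns
  rounded half away from zero; empty Cld sets, empty networks and empty
  matrices are legal and produce empty, well-typed results, while a
  grouping request on too few rows (fewer than `3 * perplexity + 2`)
  is refused with the minimum stated.
* Gene-table indices are recomputed on read with the fixed sort
  (start, end, gene id), so equal-start ties are deterministic.
* All errors are classed conditions (`cldatlas_*`), so callers can
  distinguish parse errors, lookup errors and configuration errors
  programmatically.

# Problem sizes used by the test-suite and acceptance script

The suites run the statistic-recovery checks at 200 neighborhoods per
benchmark (100 per archetype for linkage, 200 per archetype for
grouping at the full perplexity-50 / 5000-iteration embedding), 500
anchors for residue classification, 500 random graphs and 1000 random
trees for the oracle comparisons. These sizes were picked as the
smallest at which the planted effects are unambiguous (e.g. binomial
99% bounds on planted co-occurrence need a few hundred anchors) while
keeping the whole suite fast enough to run routinely.

# Known limitations

* The native clusterer is a containment heuristic: it has no E-values,
  no alignments, and single-linkage-like drift is bounded only by the
  coverage rule. Use imported clusterings for publication-grade numbers.
* Clade numbering, neighborhood-group numbering and t-SNE layouts are
  not comparable across datasets or seeds.
* The reductase screen is only as good as the profile models and the
  cutoff supplied; model names are pass-through.
* Lineage labels (1/2a/2b) are user annotations on the tree, not
  computed by the package.
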