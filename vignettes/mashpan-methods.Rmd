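---
title: "Methods: Mash-cluster pangenome mining of biosynthetic gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mash-cluster pangenome mining of biosynthetic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

*Streptomyces* genomes are so diverse that genus-wide comparisons of
biosynthetic gene clusters (BGCs) are dominated by phylogenetic noise, while
species-level comparisons starve for data (most named species have a single
genome). `mashpan` implements a middle path: group genomes by whole-genome
Mash similarity into hierarchical **Mash-clusters**, then analyse the
distribution and chromosomal synteny of BGC families within and across those
clusters. The package covers the full workflow — genome quality triage,
MinHash sketching and Mash distances, two-level K-means clustering refined by
iterative silhouette filtering, similarity-network species assignment,
regrouping of gene cluster families (GCFs) that share a MIBiG reference hit,
distribution classes per cluster, and a dual-edge synteny network with
conserved-backbone detection.

Heavy upstream annotation (antiSMASH, BiG-SLICE, BiG-SCAPE, CheckM, GTDB-Tk)
is out of scope: their outputs enter as columns of the genome-metadata and
BGC tables.

## Mash distance model

A genome is reduced to the bottom-`s` MinHash sketch of its canonical k-mers
(the lexicographic minimum of each k-mer and its reverse complement, so
sketches are strand-invariant). K-mers are pooled across contigs and never
span contig boundaries. Defaults are `k = 21` and `s = 1000`; `k` follows
the standard choice for bacterial genomes, `s = 1000` is Mash's default
(small enough to be fast, large enough that the Jaccard estimate on the
union-bottom-`s` has a standard error of a few parts per thousand). Hashing
is a seeded splitmix64 finalizer over the 2-bit-packed k-mer, truncated to
53 bits so hash values are exact in doubles; results are identical across
runs and platforms.

For two sketches the Jaccard index `j` is estimated as the fraction of the
`s` smallest union hashes present in both sketches, and converted to the
Mash distance

```
D = -log(2 j / (1 + j)) / k
```

which approximates per-base substitution divergence (roughly `1 - ANI`).
`j = 0` is capped at `D = 1` (the formula diverges), keeping the metric
bounded for clustering.

**Resolution limit.** With `s = 1000` and `k = 21`, a pairwise divergence of
`d` leaves roughly `1000 * (1-d)^21 / (2 - (1-d)^21)` shared hashes: about
486 at `d = 0.02`, 58 at `d = 0.1`, 17 at `d = 0.15` — but only ~3 at
`d = 0.2` and ~0.5 at `d = 0.25`. Beyond `d ≈ 0.2` the estimate is dominated
by Poisson noise and single pairs can hit the `j = 0` cap, producing
distance entries that jump between ~0.3 and 1.0. Distances in that regime
say "very far" but not *how* far, and downstream K-means geometry degrades.
The synthetic-data defaults keep all informative levels inside the resolving
range for exactly this reason (see below).

## Cluster-count selection and iterative filtering

Each genome is represented by its row of the Mash distance matrix; K-means
(50 restarts, fixed seed) runs for every candidate `k` (default 2–20,
truncated to `n - 1`). Each solution is scored by the **average silhouette
computed on the Mash distance matrix itself**, not on the Euclidean feature
space — silhouettes must reflect the genomic distance being interpreted. A
config switch (`silhouette_metric = "euclidean"`) restores the feature-space
convention. The chosen `k` maximizes the average silhouette; exact ties
(flat curves, e.g. structureless data) fall to the elbow of the inertia
curve — the largest second difference of the inertia normalized by the
one-cluster inertia — and finally to the smallest `k`. The normalization
("adjusted inertia") only ever breaks ties.

Genomes with silhouette below the cutoff (default 0.4) are removed, and the
sweep repeats on the retained set until no genome falls below the cutoff or
`max_rounds` (default 10) is reached; genomes still pending removal at the
cap are dropped too, so the invariant *every retained genome's final
silhouette ≥ cutoff* always holds. Each primary cluster is then
sub-clustered the same way with the same cutoff; labels are `M<i>` and
`M<i>_<j>`. Primary clusters with fewer than 3 genomes, or in which no
sub-structure survives the cutoff, pass through unsplit as `M<i>_1` with a
warning.

The workflow also mixes in the hierarchical view: `feature_rows()` emits the
Pearson correlation distance (`1 - r`) between distance-matrix rows, and the
heatmap orders genomes by Ward (ward.D2) clustering of that distance.
Hierarchical ordering is presentation only; assignments always come from the
K-means/silhouette loop. Pairs involving a constant row get correlation
distance 1 with a warning.

## Species assignment

Genomes lacking an input (GTDB-style) species label enter an undirected
graph with an edge wherever whole-genome similarity strictly exceeds 95%
(Mash distance < 0.05, a conventional species boundary). Louvain modularity
maximization at resolution 1 with a fixed seed defines novel species
(`MASH_sp_<n>`); isolated genomes become singleton species. Connected
components are reported alongside the communities so users can prefer the
coarser partition when a component contains weakly linked subgroups.

## Quality triage

Gates apply in order: (1) completeness ≤ 90% or contamination ≥ 5% → LQ;
(2) complete/chromosome assemblies → HQ; (3) more than 100 contigs or
N50 < 100 kb → LQ; (4) rest → MQ. All boundaries are read strictly
(exactly 100 contigs is MQ; completeness exactly 90 is LQ) and every
threshold is a config key, so the semantics can be flipped without touching
code. A consequence of the gate order: an assembly flagged complete but
failing the contamination gate can never be HQ.

## GCF regrouping

A GCF is **known** when at least one member BGC hits a MIBiG reference with
knownclusterblast similarity strictly above 80% of genes. A GCF hitting
several accessions is assigned one by majority of above-threshold hits
(ties: higher mean similarity, then lexicographically smaller accession) —
deterministic, and faithful to the idea that the family's identity is the
reference most of its members resemble. Known GCFs sharing an accession
merge into one regrouped family (`RGCF_<accession>`); unknown GCFs pass
through one-to-one, since without a reference hit their diversity cannot be
re-tested by this approach. The operation is idempotent and never increases
the family count. MIBiG entries encoding the same compound are *not*
auto-merged — compound identity is external knowledge — but an optional
accession-to-compound map enables compound-level merging.

Similarity bands default to the conventional coloring <50 / 50–80 / >80
(BGCs without a hit fall in the lowest band); custom break points must be
strictly increasing and span 0–100, so overlapping bands are impossible by
construction.

Distribution classes consider regrouped families with at least 5 member
BGCs: **common** (present in every Mash-cluster), **unique** (exactly one),
**accessory** (some but not all), **unassigned** (only in genomes dropped
from the clustering, which are always tallied separately). Presence-pattern
overlap counts (UpSet-style) are emitted as a table.

## Synteny network and backbone

BGCs are ordered by (contig, start) with ties broken by end then id;
overlapping BGCs are kept in start order with a warning. The network has two
edge sets: chromosomal adjacency (consecutive BGCs per contig — never across
contigs, there is no ordering evidence there) and similarity (regrouped
family co-membership cliques, or a pairwise distance list cut at 0.3, the
conventional BiG-SCAPE threshold). Because adjacency needs contiguous
coordinates, backbone analysis is most informative on complete assemblies;
plasmid contigs simply contribute separate short paths.

Backbone detection: candidate families are those present in at least
`min_presence` (default all) of the group's genomes; each genome's
chromosome order is projected onto the candidates, collapsing multi-copy
families to their first occurrence (flagged). The consensus is the
projection of the reference genome (most BGCs; ties by id), canonicalized to
the majority orientation so the result is invariant to which genomes happen
to be stored flipped — *Streptomyces* chromosomes are linear and assembly
orientation is arbitrary, so a projection equal to the exact reversal of the
consensus is "reversed", never a conflict. If some projection matches
neither direction, families are removed greedily — always the one involved
in the most pairwise order conflicts, ties lexicographic — until every
projection is consistent. The exact maximum consistent subset is
exponential; the greedy rule removes exactly the transposed family in the
single-transposition case and is deterministic. Variable regions are the
BGCs strictly between two backbone anchors, reported in consensus
orientation; dot plots pair same-family BGCs across two genomes.

## The synthetic-data generator

The generator is first-class, tested code: it plants the statistical
structure every downstream stage assumes, so the whole workflow is testable
without downloads.

*Genomes.* One root sequence; primary-cluster centers, secondary-subcluster
centers and strains are substitution-mutated copies (no indels — Mash
distance tracks substitution-only divergence cleanly) with branch rates set
to half each level's target pairwise divergence. Defaults: 3 primary × 2
secondary × 8 genomes + 3 outliers of 50 kb, pairwise divergences 0.005
(within subcluster, ~ANI 99.5%, strains of one species), 0.02 (within
primary cluster, ~ANI 98%, a group of close species) and 0.1 (between
primary clusters, genus scale) — a 5× between:within ratio. All three levels
sit inside the Mash resolving range above; pushing the between-primary level
to 0.2 makes the planted structure *undetectable in principle* at `s = 1000`
because the distance matrix itself decoheres. Outliers are placed at a
pairwise divergence of 0.15 from every clustered genome — beyond the
between-primary level (so they belong to no cluster) yet still resolvable
(~17 shared hashes), so their removal reflects the silhouette rule rather
than sketch saturation. Outliers carry no secondary truth label.

*BGC tables.* Each genome gets an ordered single-contig inventory: the
primary cluster's 7-family backbone in fixed order, variable families
(6 by default) inserted between fixed anchor pairs with probability 0.5 per
secondary subcluster, and 4 known families emitted under one GCF label per
subcluster index while sharing one MIBiG accession (similarity drawn from
Uniform(81, 100)) — the planted regrouping truth. All other BGCs carry decoy
hits at Uniform(0, 50). Coordinates are 0-based half-open, non-overlapping,
ascending. Types come from a fixed catalog of abundant product classes
(terpene, NI-siderophore, NRPS, T1PKS, …) purely as labels.

*What it does not emulate:* real gene content or GC composition, indels and
rearrangements other than the planted ones, plasmids, contig fragmentation,
horizontally transferred BGCs, or the heavily skewed cluster sizes of public
collections. Passing tests therefore demonstrate correctness of the
algorithms under the planted model, not robustness to every artifact of
real assemblies.

## Problem sizes and determinism

The shipped analyses and tests run the 51-genome design above: one
clustering study takes ~2 s, and the 20-seed recovery study ~40 s, on one
CPU. All stochastic stages (mutation draws, K-means restarts, Louvain) are
seeded; regenerating with the same seed reproduces byte-identical tables.
At publication scale (thousands of genomes) the same code paths apply; the
distance matrix is then typically ingested from a precomputed TSV via
`read_distance_matrix()` rather than sketched in-session.

## Known limitations

* Backbone detection assumes one linear chromosome per genome (multi-contig
  genomes are ordered within contigs only; circular rotation is not
  considered).
* The greedy conflict-removal rule is a heuristic; adversarial rearrangement
  patterns could remove more families than the minimal set.
* Louvain communities can split a weakly-linked connected component into
  several species; the component partition is exported for users who prefer
  the coarser view.
* Mash distances beyond ~0.2 (at `s = 1000`, `k = 21`) are saturation-noisy;
  interpret cluster structure at that range with care or increase `s`.
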