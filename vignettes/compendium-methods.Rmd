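---
title: "Methods: compendium assembly, structural statistics, and the planted-truth generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compendium assembly, structural statistics, and the planted-truth generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical and algorithmic choices behind
`pkncompendium`: what each statistic assumes, which knobs matter, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The data model

A *compendium* merges two kinds of inputs that are kept strictly separate in
provenance:

* **Pathway records** — (label, source database, gene set) triples. No
  attempt is made to harmonize labels across databases: "EGFR1 signalling"
  in one source and "EGF receptor signalling" in another remain two records.
  A gene's *Pathway Maps* is therefore a count of database-scoped records.
* **Interaction records** — gene pairs with per-source direction
  (forward/reverse/undirected relative to the canonical pair order), sign
  (positive/negative/unsigned) and mechanism (direct/indirect/unknown).

**Edge identity is the unordered canonical pair** (`gene_a <= gene_b`
lexicographically). Direction is an annotation, not part of identity. This
makes the edge weight `K_E` (number of distinct sources reporting a pair)
and the edge consistency `C_E` well-defined across mixed directed/undirected
dialects, at the cost of conflating a directed A→B report with an undirected
A–B report at the counting level. A directed multigraph *view* is derived
from the annotations for path analysis, so no directional information is
lost — it is only excluded from pair-level bookkeeping.

Other assembly rules: the master gene list is the union of the pathway gene
sets, and interactions are kept only when **both** endpoints are on it;
self-loops are dropped at ingestion (counted in the load report); molecular
complexes expand combinatorially to all `choose(n, 2)` undirected pairs;
identifier mapping is a verbatim two-column table (no live lookups), with
unmapped identifiers passing through under a warning. Unknown SIF relation
strings never fail a load — they map to (undirected, unsigned, unknown) with
the raw string preserved.

## 2. Structural statistics

**Degree.** Two mean-degree conventions are reported side by side:
`n_edges / n_nodes` (the convention in which a dense multi-source compendium
reads ≈27) and the graph-theoretic `2 n_edges / n_nodes`. The output labels
them explicitly because the two differ by a factor of 2 and both appear in
the literature.

**Betweenness** is computed on the undirected projection with unit edge
lengths, endpoints excluded, normalized by the number of vertex pairs so
values are fractions in [0, 1] (the middle node of a 3-node path scores 1).
The mixed directed/undirected provenance of real compendia makes the
undirected projection the only reading that is reproducible across sources;
this matches what general-purpose network tools report.

**Hypergeometric Z.**
`Z = (r − nR/N) / sqrt(n (R/N)(1−R/N)(N−n)/(N−1))`. When the standard
deviation is zero — the window covers the whole network (`n = N`), or the
category is empty or universal — the sample equals its expectation by
construction and `Z` is defined as 0. `|Z| > 2` corresponds approximately to
p < 0.05.

**Enrichment scan.** The landscape scan needs a deterministic ranking
"toward the tip" of a region of the Pathway-Maps × betweenness plane, which
is not fully specified by the region names alone. The package scores each
gene by the product of its percentile ranks in the region's preferred
directions (e.g. `pct(Maps) · pct(B_T)` for the hi/hi region), breaking ties
lexicographically by gene id, and widens the sample window from the top 10
genes to the whole network (optionally decimated via `n_windows`). Any
monotone scoring rule gives qualitatively similar landscapes; the product of
percentiles is symmetric in the two axes and scale-free.

**Jaccard similarity and ordering.** Pathway similarity is the plain Jaccard
index; the heatmap ordering is agglomerative **average linkage on 1 − J**,
hand-rolled so that tie-breaking is deterministic: among equal merge
distances the lexicographically smallest index pair merges first, and the
longer-established cluster stays on the left. An all-tied matrix therefore
preserves input order — a property `stats::hclust` does not guarantee — and
tie-free matrices produce the same merge tree as `hclust(method =
"average")` (verified in the tests). The same ordering rule is applied to
consistency and modularity matrices on Euclidean row-profile distances
(missing cells mean-imputed *for ordering only*).

**Edge consistency.** `C_E(i, j) = e(i, j) / E(i)` where `E(i)` counts
database *i*'s edges whose both endpoints are touched by database *j*'s
edges, and `e(i, j)` those also present in *j*. A database's gene set is
*induced from its edges* because interaction sources carry no independent
gene roster inside a compendium. `E(i) = 0` yields a flagged `NA`, never 0.
Comparison ignores direction and sign (pair-level, like `K_E`).

## 3. Pathway modularity and its null

For a pathway with member set *G* and an edge set: every internal edge (both
endpoints in *G*) contributes 2 to `P_IN`, every external edge (exactly one
endpoint in *G*) contributes 1 to `P_EX`, and `P_T = P_IN + P_EX` is exactly
the degree sum of the member genes. This endpoint-counting convention is the
only reading under which the decomposition identity holds with `P_T` a
degree sum.

The null preserves what pathway annotations cannot explain away: each gene's
Pathway Maps and each pathway's size are held fixed while the bipartite
membership incidence is shuffled by random pairwise swaps (a compiled
kernel; 10× the incidence count of attempted swaps by default; R's RNG, so
seeded runs reproduce). The expected ratio `E_IN/E_T` is the per-pathway
mean over `n_randomizations` whole-table randomizations (default 100;
a pooled variant is available via `pooled = TRUE`), and

> `M = (P_IN/P_T) / (E_IN/E_T) − 1`

so `M = 0` is random and `M = 1` is two-fold more internal edges than
expected by chance. Significance per (pathway database × interaction
network) cell is a **one-sided** Mann–Whitney test of the observed-ratio
distribution against the expected-ratio distribution — one-sided because
modularity is a directional claim; the two-sided test is available through
`mann_whitney_u`. The U statistic uses midranks; p-values come from full
arrangement enumeration when `choose(n1 + n2, n1) <= 2e5` and from the
tie-corrected normal approximation with continuity correction otherwise.

Degenerate cases are flagged, not fudged: a pathway whose members touch no
edge has undefined ratio; `E_IN/E_T = 0` leaves `M` as `NA`; a single-record
pathway table has no swap degrees of freedom and randomizes to itself.

## 4. The synthetic generator: a stated world

`generate_compendium` emulates the statistical regularities of real
multi-source compendia:

* **Pathway multiplicity**: per-gene Pathway Maps from a truncated discrete
  power law `P(m) ∝ m^−α`, `m = 1..cap` (defaults α = 2, cap = 10; every
  gene belongs to at least one pathway, so the master list is the gene
  universe). α = 2 puts the majority of genes in exactly one pathway, the
  regime observed in curated collections. Pathway sizes are drawn uniformly
  from a range centred on the capacity implied by the multiplicities, then
  memberships are laid out by stub matching with duplicate repair —
  realized sizes stay inside the configured range and multiplicities are
  preserved up to the capacity reconciliation.
* **Edge sharing**: each source generates `n_edges_per_source` distinct
  pairs; every edge is then copied into each other source independently
  with probability `source_sharing`. `K_E − 1` is Binomial(S−1, p), so small
  `p` reproduces the heavy-tailed, mostly single-source edge-weight
  distribution (e.g. `(1−p)^{S−1} ≈ 0.81` of edges single-source at
  `p = 0.1`, `S = 3`), and the mean is `1 + p(S−1)` up to pair collisions.
* **Annotations**: direction, sign and mechanism are drawn independently
  per (edge, source) from the configured fractions; a `n_meta_datasets`
  option makes the first source a meta-database whose edges carry multiple
  per-dataset sub-annotations.
* **Planted modularity** (`internal_edge_enrichment`, see below).
* **Planted scaffolds** (`generate_scaffold_network`): a directed ligand →
  effector chain, exactly `n_bypass` arcs from the chain head that skip the
  second node (the receptor), and `n_intermediates` one-step detours between
  scaffold pairs. Background edges never point *into* the scaffold, so the
  planted elements are exactly the recoverable ones — which is what makes
  exact planted-truth tests possible.

### Calibrating the enrichment knob

The natural knob — accept within-pathway candidate pairs at odds *w*
relative to other pairs — does **not** satisfy `M ≈ w − 1`. Three effects
shrink the recovered score: the observed ratio's denominator includes the
planted internal edges; pathway overlap makes nominally "external" edges
enriched as well; and the Maps-preserving null overweights
high-multiplicity genes, whose degrees rise with the planting. Under a
literal propensity knob at `w = 2`, the recovered mean `M` is roughly 0.4
in the default world — a property of the statistic, not a bug.

`pkncompendium` therefore defines `internal_edge_enrichment = e` in the same
units as `M` itself: **the target fold-enrichment of a pathway's internal
fraction over the membership-randomization null** (`M + 1`). The generator
solves for the acceptance odds analytically, then refines over a few
regeneration passes until the realized edge set carries the target fold as
measured by a closed-form null (multiplicity-weighted inclusion
probabilities evaluated on the realized edges — independent of the swap
machinery, and agreeing with it to ~0.1% in the tested regimes). The loop is
deterministic given the seed, keeps the best pass, and stops at |fold − e| <
0.01. The literal `"propensity"` mode and a `"fold_vs_uniform"` mode
(internal edge *count* at `e` times its uniform-placement expectation)
remain available for users who want the raw knob.

What the generator does **not** emulate: correlated annotation errors
between sources, hub-biased (preferential-attachment) degree distributions
beyond what pathway overlap induces, literature-curation artefacts such as
label drift, or any fitting to a particular real compendium's exact
distributions. A green planted-truth test therefore establishes estimator
correctness under the stated world, not fidelity of that world to any
particular database snapshot.

## 5. Path analysis

The directed view keeps one arc per ordered pair supported by at least one
annotation passing the filter (directed-only by default, with optional
source/mechanism/sign/weight filters). Bounded enumeration counts **simple**
paths — node revisits would make the counts diverge — by an iterative
(explicit-stack) depth-first search with an on-path marker, to a maximum
length of 8 edges by default and a configurable ceiling of 10⁷ paths beyond
which the result is flagged truncated. Per-length counts are exact lengths;
cumulative counts are also reported since published per-length figures can
follow either convention. The through-fraction is computed exactly as
`1 − paths(G − v)/paths(G)` (deletion, not sampling); `position =
"first_hop"` restricts to routes whose first step is the required node.
Scaffold expansion scans *all* ordered scaffold pairs for one-step
intermediates and classifies each link: parallel (`j = i + 1`),
feed-forward (`i < j − 1`), feed-back (`i ≥ j`). Scaffold edge-weight
enrichment is the upper-tail hypergeometric probability of the observed
number of high-`K_E` edges among the scaffold's consecutive edges.

## 6. Numerical and engineering choices

* Canonical order is R string comparison; identifiers are expected to be
  ASCII gene symbols.
* All stochastic functions take explicit seeds and restore the caller's RNG
  state (`withr::with_seed`); the Rcpp swap kernel draws from R's RNG so
  compiled and interpreted paths share one seeded stream.
* Configuration files are JSON (no YAML parser in the supported stack);
  every pipeline run echoes its effective configuration and writes an MD5
  manifest, and a write → read → write cycle of a compendium is
  byte-identical.
* Betweenness and all-shortest-paths delegate to igraph; the test suite
  checks both against independent BFS/enumeration oracles rather than
  trusting the library.

## 7. Known limitations

* Pair-level edge identity cannot distinguish a genuinely undirected
  interaction from ignorance of direction; both count once toward `K_E`.
* The modularity null conditions on the annotation structure (Maps, sizes)
  but not on the network's degree sequence; it answers "are these
  particular gene sets unusually self-connected?", not "is the graph
  modular?".
* Exhaustive path enumeration is exponential in the length bound; the
  ceiling truncates rather than approximates, and truncated results should
  not be compared across graphs.
* The closed-form calibration null is accurate in the tested regimes
  (hundreds of genes, tens of pathways, multiplicity cap well below the
  pathway count) but degrades when single genes approach membership in all
  pathways.
* `enrichment_scan` assumes every gene has a function category; genes
  without annotation are treated as the literal category `"other"`.
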