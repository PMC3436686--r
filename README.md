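# pkncompendium

Tools for building and dissecting **prior knowledge networks (PKNs)** of
signal transduction: merge pathway gene sets and protein-interaction edge
lists from multiple on-line databases into a single provenance-annotated
*compendium*, then quantify what that ensemble actually looks like —
how consistent the sources are with each other, whether annotated pathways
form network modules, and how many alternative (often biochemically
implausible "bypass") routes connect a ligand to its downstream effectors.

The package is aimed at systems biologists who assemble PKNs as the starting
topology for logic-based or kinetic models and need to know how much of that
topology to trust.

## What it computes

* **Ensemble assembly** (`build_ensemble`): pathway tables (long TSV or
  GMT), interaction files (Cytoscape SIF or annotated TSV), combinatorial
  complex expansion, master-list filtering, canonical unordered-pair edge
  identity with per-source direction/sign/mechanism annotations.
  Each edge carries its *Edge Weight* `K_E`, the number of source databases
  reporting it; each gene its *Pathway Maps*, the number of database-scoped
  pathway records containing it.
* **Topology** (`compute_degrees`, `compute_betweenness`,
  `hypergeometric_z`, `enrichment_scan`): per-gene degree and betweenness
  `B_T` (fraction of all shortest paths through a gene), and the
  sliding-window hypergeometric enrichment landscape
  `Z = (r − nR/N) / sqrt(n (R/N)(1−R/N)(N−n)/(N−1))`
  that localizes kinases, transcription factors, and binding proteins in the
  Maps-vs-betweenness plane.
* **Pathway similarity** (`similarity_matrix`): all-pairs Jaccard index
  `J(i,j) = |i ∩ j| / |i ∪ j|` with deterministic average-linkage ordering.
* **Edge concordance** (`edge_weight_distribution`, `consistency_matrix`):
  K_E histograms and the directional *Edge Consistency*
  `C_E(i,j) = e(i,j) / E(i)` between every pair of interaction sources.
* **Pathway modularity** (`modularity_scores`, `modularity_matrix`): the
  internal-edge fraction `P_IN/P_T` of each pathway against its expectation
  under membership randomization that preserves every gene's Pathway Maps
  and every pathway's size; the score `M = (P_IN/P_T)/(E_IN/E_T) − 1` is 0
  for random edge placement and 1 for two-fold enrichment, with Mann–Whitney
  significance.
* **Path analysis** (`directed_view`, `enumerate_paths`,
  `through_fraction`, `expand_scaffold`, `scaffold_edge_enrichment`):
  bounded simple-path enumeration by iterative depth-first search, all
  shortest paths, the fraction of routes passing through a required
  intermediate (its complement is the bypass fraction), and one-step
  expansion of a linear scaffold into parallel, feed-forward and feed-back
  intermediates.
* **Synthetic worlds with planted truth** (`generate_compendium`,
  `generate_scaffold_network`): multi-database compendia with power-law
  pathway multiplicities, tunable cross-source edge sharing, calibrated
  within-pathway edge enrichment, and planted signalling scaffolds with
  known bypass edges and intermediates — ground truth for every stage.
* **Pipeline** (`simulate_inputs`, `run_pipeline`, `inst/cli/compendium-cli.R`):
  JSON-configured end-to-end runs with checksum manifests; identical
  configuration and seed give identical outputs.

## Worked example

```r
library(pkncompendium)

cfg <- synthetic_config(n_genes = 300, pathway_sources = c(dbA = 8L, dbB = 8L),
                        n_edges_per_source = 800, internal_edge_enrichment = 2,
                        source_sharing = 0.1, seed = 42)
gen  <- generate_compendium(cfg)
comp <- gen$compendium
summary(comp)
#> genes: 300  pathway records: 16  canonical edges: 2325
#> mean degree: 7.8 (edges/nodes convention), 15.5 (graph convention)
#> edge weight distribution:
#>    1    2    3
#> 1818  475   32

res <- modularity_scores(comp, n_randomizations = 100, seed = 43)
mean(res$m, na.rm = TRUE)
#> [1] 1.00   # the planted two-fold internal enrichment, recovered

round(consistency_matrix(comp)$values, 2)
#>        intdbA intdbB intdbC
#> intdbA   1.00   0.19   0.22
#> intdbB   0.19   1.00   0.20
#> intdbC   0.22   0.19   1.00

hypergeometric_z(N = 100, R = 10, n = 10, r = 5)
#> [1] 4.4222
```

Reading the output: most edges are single-source (`K_E = 1`) because the
sharing probability is low, reproducing the heavy-tailed edge-weight
distribution seen in real multi-database compendia; pairwise edge
consistencies around 0.2 mean each source confirms only ~20% of another
source's edges on their shared genes; and the mean modularity `M = 1.0`
recovers the planted two-fold internal edge enrichment exactly.

## Documentation

The methods vignette (`vignettes/compendium-methods.Rmd`) describes the
statistics, the randomization null, the synthetic-data generator and its
calibration, numerical choices, and known limitations.
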