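# axonmod

Network-medicine toolkit for locating disease genes on a protein-protein
interaction network and comparing the resulting disease modules — built
around the workflow used to study genetically heterogeneous axonal
disorders (Charcot-Marie-Tooth type 2 and hereditary spastic paraplegia),
and exercisable end to end on synthetic networks.

## What it computes

Given an interactome *G* (N nodes) and curated seed gene sets:

* **Localization.** The size *S* of the largest connected component (LCC)
  of the seed-induced subgraph, with a z-score against random node sets of
  equal size (proto-module: z ≥ 1.6, empirical p ≤ 0.05), and the
  nearest-seed shortest-distance distribution *d_s* with a one-sided
  Mann-Whitney U test against randomized sets.
* **Separation.** For two seed sets A, B the network separation

  ```
  s_AB = d_AB − (d_AA + d_BB) / 2
  ```

  where d_AA, d_BB are mean nearest-neighbor distances within each set and
  d_AB across them (shared genes contribute 0). s_AB < 0 with z ≤ −1.6
  means topologically overlapping modules; s_AB > 0 with z ≥ 1.6 means
  separated ones. The default null resamples sets degree-binned to control
  hub bias.
* **Expansion (DIAMOnD).** Iterative module growth by hypergeometric
  connectivity significance P(X ≥ k_s) for a candidate with degree k and
  k_s links into the current module of size s0, with seed weight ω
  (module links counted ω-fold; recommended ω = 10, 200 iterations).
* **Validation.** Wang-method GO semantic similarity (is_a 0.8, part_of
  0.6, max-rule S-value propagation) combined per gene pair by best-match
  average, after excluding IEA/IPI evidence codes; hierarchical clustering
  of the similarity matrix.
* **Interpretation.** Module-set algebra (core/spectrum/exclusive sets of
  two expanded modules), hypergeometric over-representation analysis with
  BH-FDR (filter FDR ≤ 0.2), Jaccard (> 0.1) grouping of redundant
  pathways, and dominance assignment of each pathway to a disease module.
* **Synthetic data.** Scale-free interactomes, planted modules with
  controllable cohesion and overlap, toy ontologies/annotations/pathway
  collections, and hide-and-recover splits — so calibration and recovery
  claims are testable without downloads.

## Worked example

```r
library(axonmod)

g <- generate_scale_free(2000, 3, rng_seed = 42)       # synthetic interactome
seeds <- plant_module(g, 30, cohesion = 1.0, rng_seed = 7)

lcc_significance(g, seeds, n_rand = 1000, rng_seed = 1)
#> LCC of 'planted': S = 30 of 30 seeds (null 1.88 +/- 0.73 over 1000 randomizations)
#>   z = 38.31, empirical p = 0.000999 -> proto-module (z >= 1.6, p <= 0.05)

pair <- plant_overlapping_pair(g, 30, 30, overlap = 15, cohesion = 0.9,
                               rng_seed = 5)
separation_significance(g, pair$module_a, pair$module_b,
                        n_rand = 200, rng_seed = 7)
#> Separation planted_A (n=30) vs planted_B (n=30): s_AB = -0.350 (d_AA 1.17, d_BB 1.03, d_AB 0.75)
#>   z = -2.21, p = 0.027, shared nodes = 15 -> overlapping (degree_binned null, 200 randomizations)

hidden <- hide_members(seeds, 0.5, rng_seed = 21)
dr <- diamond_expand(g, hidden$visible, n_iter = 50, omega = 10)
glance(dr)
#> # A tibble: 1 × 6
#>   seed_name omega n_seeds n_added n_members last_p_value
#>   <chr>     <dbl>   <int>   <int>     <int>        <dbl>
#> 1 seeds        10      15      50        65     1.03e-11
mean(hidden$hidden %in% dr$module$diamond_nodes)
#> [1] 0.6
```

The planted module of 30 genes is recovered as a maximal proto-module
(all 30 seeds in one connected component, z far above the 1.6 threshold);
the two modules planted with 50% shared genes are read as topologically
overlapping (negative s_AB, z ≤ −1.6); and DIAMOnD re-discovers 60% of
the hidden planted members within 50 iterations, far above the chance
rate for degree-matched nodes (50 of 2000).

The methods vignette (`vignettes/disease-modules.Rmd`) documents the
models, the null-model choices, the synthetic study conditions, and known
limitations.

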