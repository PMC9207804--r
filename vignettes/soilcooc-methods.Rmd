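---
title: "Methods: co-occurrence networks along a pH gradient"
author: "soilcooc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks along a pH gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcooc)
```

## The analysis in one paragraph

Soil bacteria and fungi respond strongly to pH, and taxa that share an
environmental preference tend to co-occur. `soilcooc` turns an OTU count
table and a table of edaphic variables into a signed co-occurrence network
and a set of derived statistics: which taxa are "core" to the community,
which pairs co-occur more strongly than chance, how the network's topology
varies from sample to sample, which taxa form pH-preference ecological
clusters, how specialized each taxon's habitat use is (Levins' niche
breadth), which nodes are putative keystone taxa in Zi–Pi space, how
gracefully the network degrades as nodes are removed (natural
connectivity), and how much of the topological variation each environmental
variable explains (MRM and Mantel tests on distance matrices).

## Pipeline stages and their parameters

1. **Closure.** Counts are converted to relative abundances per sample
   (`to_relative()`). All ranking, correlation and niche statistics operate
   on proportions; Levins' B is invariant to this choice.
2. **Core-taxon filter** (`select_core()`). A taxon is core when it is in
   the top `top_frac = 0.2` of its kingdom by mean relative abundance *and*
   detected in strictly more than `min_prev = 0.6` of samples. The two
   filters are applied as an intersection, per kingdom, because bacterial
   and fungal core sets are reported separately in this literature; joint
   ranking is available with `per_kingdom = FALSE`. Abundance ties are
   broken by taxon id so the cut is deterministic.
3. **Correlation** (`spearman_all_pairs()`). Spearman's rho on mid-ranks
   for every pair of core taxa, two-sided p from the t approximation with
   n − 2 degrees of freedom (adequate at n ≈ 90 samples; an exact
   permutation p would be prohibitive over ~10^4–10^6 pairs), and
   Benjamini–Hochberg q-values over all pairs. Constant taxa are flagged
   with rho = 0, p = 1 rather than erroring, so degenerate simulated taxa
   cannot crash a run. The unnamed "FDR correction" of common practice is
   taken to be BH, the field default.
4. **Network** (`build_network()`). Edge iff `|rho| > 0.6` and `q < 0.01`,
   both strict. The absolute value is the default because thresholding on
   raw rho cannot produce the substantial negative-edge fractions these
   networks are reported to contain; `use_abs = FALSE` restores the
   literal positive-only reading. Core taxa with no surviving edge are
   dropped from the node set. Edges carry sign and a BB/BF/FF kingdom-pair
   label.
5. **Topology** (`node_features()`, `network_features()`,
   `per_sample_topology()`). Degree, betweenness, closeness and
   eigenvector centrality per node; ten network-level features (node and
   edge counts, average degree, average path length over connected pairs,
   density, modularity, global transitivity, and Freeman centralization of
   degree, betweenness and eigenvector centrality, each normalized by its
   star-graph maximum). Per-sample subnetworks are the subgraphs induced on
   taxa detected in that sample; their edge/node ratio is the network
   *complexity*, defined as 0 for an empty subgraph to avoid 0/0.
   Numerical choices: closeness uses per-component normalization
   `(n_c − 1)/Σd` (per-sample subgraphs are routinely disconnected; a
   harmonic variant is available); eigenvector centrality is a power
   iteration on `A + I` over the largest component (the shift shares the
   Perron vector and cannot oscillate on bipartite components), zero
   elsewhere, scaled to max 1 — iterative eigensolvers with random starts
   would break bit-reproducibility; modularity is computed on the module
   partition, re-detected per subnetwork with a fixed seed.
6. **Ecological clusters and niche breadth** (`assign_clusters()`,
   `niche_breadth()`). A taxon is `high_pH`/`low_pH` when its abundance has
   a significant (raw p < 0.05, per the stated convention; an FDR switch
   exists but is off) positive/negative Spearman correlation with pH,
   `other` otherwise. Levins' B = 1/Σ_j p_ij² ranges from 1 (single-sample
   specialist) to N (perfectly even generalist); groups are compared with
   a Welch t-test by default (the pooled-variance test by flag).
7. **Modules and keystones** (`detect_modules()`, `zi_pi()`,
   `classify_roles()`). The default module detector is greedy modularity
   maximization; multilevel (Louvain) and an MCL-style flow clustering
   (expansion/inflation of the column-stochastic adjacency with self-loops)
   are provided because Markov-clustering-based pipelines exist in this
   literature and the original method is ambiguous. All are deterministic
   per seed; isolated nodes become singleton modules. Zi is the z-score of
   within-module degree against the node's module (population sd; a module
   of interchangeable nodes has no hubs, so sd = 0 gives Zi = 0); Pi is the
   participation coefficient 1 − Σ_s(k_is/k_i)², 0 for isolated nodes.
   Roles split at Zi = 2.5 and Pi = 0.62 with boundaries assigned downward;
   connectors, module hubs and network hubs are flagged keystone.
8. **Robustness** (`natural_connectivity()`, `robustness_curve()`).
   Natural connectivity ln((1/N)Σ exp(λ_i)) over the adjacency eigenvalues,
   computed by a dense symmetric eigendecomposition with a log-sum-exp
   guard (fine to a few thousand nodes). Nodes isolated by removal stay in
   N (they contribute e⁰), keeping the statistic size-normalized. Removal
   of ⌊fN⌋ uniformly sampled nodes, default fractions 0–0.8 in steps of
   0.05 and 100 replicates (the source conventions are unstated; these are
   documented defaults).
9. **Drivers** (`mrm()`, `mantel_test()`, `feature_driver_table()`,
   `edge_count_driver_analysis()`, `screen_env()`). MRM regresses the
   lower triangle of a response distance matrix on predictor distance
   matrices; inference permutes the response's rows and columns jointly
   (predictors never permuted), p = (1 + #{|stat*| ≥ |stat|})/(1 + R) with
   R = 999 by default; Mantel tests use R = 9,999. The per-variable
   variance share is the squared semi-partial correlation
   (R²_full − R²_−j); how the original tables were decomposed is unstated,
   and this choice is recorded in the output metadata. Environmental
   variables are z-scored before Euclidean distances so units do not leak
   into the geometry, and `screen_env()` implements the ρ² < 0.6
   collinearity retention rule with pH protected.

## The synthetic community generator

No public dataset accompanies the analysis this package operationalizes, so
`simulate_community()` plants every signal the pipeline is supposed to
recover and ships the ground truth alongside.

* **Environment.** 90 samples spread over pH 4.5–9 (evenly spaced plus
  jitter, endpoints forced), with 19 covariates that are noisy linear
  functions of pH at target correlation 0.4 — a stand-in for the collinear
  edaphic factors of a real survey.
* **Taxa.** 600 bacteria and 100 fungi, each with a Gaussian pH response
  (optimum, tolerance), a lognormal baseline abundance, and a ground-truth
  cluster given by the side of the gradient midpoint its optimum falls on.
  Low-pH taxa draw tolerances of 0.3–1.0 pH units and high-pH taxa 1.0–2.0:
  low-pH specialists versus high-pH generalists, the asymmetry implied by
  the narrower niche breadth and tighter interactions reported for low-pH
  communities — and the mechanism that makes per-sample network complexity
  fall with pH in the generated data (Pearson r ≈ −0.6 to −0.8 at the
  default conditions).
* **Guilds.** 8 guilds covering half the pool, sampled with weight 0.8
  toward low-pH taxa. Guild members share one standard-normal latent factor
  per guild per sample, scaled by a per-taxon strength in [0.6, 1]; this is
  the minimal mechanism that induces true positive co-occurrence beyond
  shared environmental response. Negative associations arise implicitly
  from opposed pH optima; there is no explicit antagonism term.
* **Counts.** Expected relative abundance ∝ baseline × Gaussian response ×
  exp(strength × latent). Per-cell rates are Gamma(shape = dispersion)
  around those expectations — negative-binomial marginals — and a final
  multinomial draw conditions each sample on exactly `depth = 20000` reads,
  so depth is exact while overdispersion is preserved.
* **Seeds.** One top-level seed expands into independent substream seeds
  per stage; identical seeds give byte-identical outputs.

What the generator does *not* emulate: compositional coupling beyond the
fixed-depth constraint, phylogenetic correlation among taxa, spatial
autocorrelation between sites, sequencing artifacts (chimeras, OTU-picking
noise), and abundance distributions calibrated to any particular survey
(no quantitative description of the source community's abundance structure
is available; the lognormal baseline is a convention). Passing recovery
tests therefore demonstrates that the pipeline's inferences are correct
*when its assumptions hold*, not that they are robust to every property of
real amplicon data.

### Known limitations

* Natural connectivity grows with subgraph size and edge count. Under the
  default conditions the prevalence filter retains roughly 2.5× more
  high-pH (broad-tolerance) than low-pH core taxa, so the high-pH cluster
  subgraph has the higher natural connectivity even though low-pH samples
  host the more complex subnetworks. A field observation that the low-pH
  cluster is *more* robust implies a low-pH subgraph far denser than these
  mechanisms produce; the suite therefore asserts the size-controlled
  version of the ordering (a planted dense cluster dominates a sparse one
  at every removal fraction) rather than the cluster-labelled one.
* Correlation networks are not interaction networks: thresholded Spearman
  edges conflate shared environmental response with direct association by
  construction. The guild latent factor exists precisely so tests can ask
  whether *true* associations are enriched among inferred edges (they
  are; one-sided Fisher test), not to claim the reverse.
* The t-approximation p-value is slightly anticonservative at very small n;
  for n < 10 samples a permutation test would be preferable (the network
  stage is built for gradient surveys with tens of samples).

## Test problem sizes

Oracle-equivalence checks run on ≥20 random instances of ≤30 taxa/nodes
against brute-force implementations (rank-then-Pearson correlation,
hand step-up FDR, BFS path counting, dense eigendecompositions, per-node
tallies). Null calibration uses 500 simulations at 30 samples with 99
permutations each. Recovery checks run the full pipeline on 20 seeds of the
default 90-sample, 700-taxon conditions. These sizes were chosen to keep
the suite comfortably fast on a laptop while leaving each check
statistically sharp.
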