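# soilcooc

Co-occurrence network analysis for soil (and other) microbiome surveys
along environmental gradients, with soil pH as the motivating driver.

Microbial taxa that share a niche tend to rise and fall together across
samples. Given an OTU count table (taxa × samples, bacteria and fungi), an
environmental table (samples × variables, pH among them), `soilcooc`
builds the thresholded, signed Spearman co-occurrence network of the core
community and asks the questions ecologists ask of such networks:

* **Core taxa** — which taxa are in the top 20% by mean relative abundance
  *and* present in more than 60% of samples (per kingdom)?
* **Network** — which core pairs have |Spearman ρ| > 0.6 at
  Benjamini–Hochberg FDR q < 0.01? Edges are signed and labelled
  bacteria–bacteria / bacteria–fungi / fungi–fungi.
* **Topology** — node centralities (degree, betweenness, closeness,
  eigenvector) and ten network-level features; per-sample induced
  subnetworks and their edge/node **complexity**.
* **Ecological clusters** — high-pH vs low-pH taxa by the sign of their
  significant (P < 0.05) Spearman correlation with pH, and Levins' niche
  breadth `B_i = 1 / Σ_j p_ij²` (1 = single-sample specialist, N = perfectly
  even generalist).
* **Keystone taxa** — within-module connectivity
  `Zi = (k_i,own − mean)/sd` and participation coefficient
  `Pi = 1 − Σ_s (k_is/k_i)²`; connectors (Pi > 0.62), module hubs
  (Zi > 2.5) and network hubs (both) are putative keystones.
* **Robustness** — natural connectivity `ln((1/N) Σ_i exp(λ_i))` of the
  adjacency spectrum under repeated random node removal, per ecological
  cluster.
* **Drivers** — multiple regression on distance matrices (MRM) and Mantel
  tests with joint row/column permutation, attributing variation in
  per-sample topology and edge counts to each environmental variable.

Because the motivating survey's data are not publicly deposited, the
package ships a seed-deterministic synthetic community generator
(`simulate_community()`) that plants pH preferences, guild-driven
co-occurrence and ground-truth labels, so the entire pipeline is testable
end to end.

## Worked example

```r
library(soilcooc)

sim  <- simulate_community(seed = 42)   # 90 samples, 600 bacteria + 100 fungi
rel  <- to_relative(sim$otu)
core <- select_core(rel)
core
#> Core taxa: 127 of 700 retained (top 20% by mean abundance, prevalence > 60%)
#>    bacteria=110, fungi=17

net <- build_network(spearman_all_pairs(rel, core$taxon_ids), rel)
net
#> Co-occurrence network: 111 nodes, 2560 edges
#>   positive 1611 (62.9%), negative 949 (37.1%)
#>   BB 1834 | BF 673 | FF 53

cl <- assign_clusters(rel, sim$env$pH)
table(cl$cluster)
#> high_pH  low_pH   other
#>     326     315      59

b   <- niche_breadth(rel)
lab <- setNames(cl$cluster, cl$taxon_id)
round(tapply(b[names(lab)], lab, mean, na.rm = TRUE), 1)
#> high_pH  low_pH   other
#>    52.5    23.9    40.0

cx <- vapply(colnames(rel), function(s)
  sample_subnetwork(net, sim$otu, s)$complexity, numeric(1))
cor(cx, sim$env$pH)
#> [1] -0.6915961
```

Reading the numbers: 16 of the 127 core taxa lose every correlation at the
thresholds and drop out of the node set; roughly a third of the retained
edges are negative (mostly between taxa of opposite pH preference); the
low-pH cluster has markedly narrower niche breadth than the high-pH one
(specialists vs generalists); and per-sample network complexity falls
steeply with pH — acidic samples host the more densely connected
subnetworks.

`run_pipeline(pipeline_config(seed = 42), "results/")` runs every stage in
order and writes CSV/JSON/GraphML outputs plus a provenance manifest;
reruns with the same config are bit-identical. A thin command-line wrapper
lives at `inst/scripts/soilcooc-pipeline.R`.

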