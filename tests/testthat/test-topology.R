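test_that("node features on canonical small graphs", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  nf <- node_features(star)
  expect_equal(nf$degree, c(3, 1, 1, 1))
  expect_equal(nf$closeness[1], 1)

  path <- igraph::make_graph(~ a - b, b - c)
  nfp <- node_features(path)
  expect_equal(nfp$betweenness[nfp$node == "b"], 1)
  expect_equal(nfp$betweenness[nfp$node != "b"], c(0, 0))
})

test_that("all four node features match brute-force oracles on random graphs", {
  for (s in 1:8) {
    adj <- random_adj(15, p = 0.25, seed = s)
    g <- adj_to_igraph(adj)
    nf <- node_features(g)
    expect_equal(nf$degree, unname(rowSums(adj)))
    expect_equal(nf$betweenness, oracle_betweenness(adj), tolerance = 1e-9)
    expect_equal(nf$closeness, oracle_closeness(adj), tolerance = 1e-9)
    expect_equal(nf$eigenvector, oracle_eigenvector(adj), tolerance = 1e-9)
  }
})

test_that("network-level features on canonical graphs", {
  star <- igraph::make_star(7, mode = "undirected")
  fs <- network_features(star)
  expect_equal(fs$degree_centralization, 1)

  k5 <- igraph::make_full_graph(5)
  fk <- network_features(k5)
  expect_equal(fk$density, 1)
  expect_equal(fk$clustering_coefficient, 1)
  expect_equal(fk$degree_centralization, 0)
  expect_equal(fk$average_degree, 4)
  expect_equal(fk$average_path_length, 1)
})

test_that("two disjoint triangles have modularity 1/2 on the component partition", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  mem <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), letters[1:6])
  part <- structure(list(membership = mem, method = "manual", seed = 0,
                         n_modules = 2L), class = "module_partition")
  fs <- network_features(g, partition = part)
  expect_equal(fs$modularity, 0.5)
})

test_that("average path length excludes disconnected pairs", {
  path <- igraph::make_graph(~ a - b, b - c)
  expect_equal(average_path_length(path), 4 / 3)
  expect_equal(average_path_length(igraph::make_full_graph(4)), 1)
  for (s in 1:3) {
    adj <- random_adj(30, p = 0.08, seed = 40 + s)
    d <- oracle_distances(adj)
    vals <- d[upper.tri(d)]
    expected <- mean(vals[is.finite(vals) & vals > 0])
    expect_equal(average_path_length(adj_to_igraph(adj)), expected,
                 tolerance = 1e-9)
  }
})

test_that("complexity is edges over nodes with an empty-graph convention", {
  tri <- igraph::make_full_graph(3)
  expect_equal(complexity(tri), 1)
  tree <- igraph::make_tree(10, children = 2, mode = "undirected")
  expect_equal(complexity(tree), 9 / 10)
  expect_equal(complexity(igraph::make_empty_graph(0, directed = FALSE)), 0)
})

test_that("per-sample subnetworks are induced subgraphs of the network", {
  sim <- small_sim(seed = 51)
  rel <- to_relative(sim$otu)
  net <- build_network(spearman_all_pairs(rel, select_core(rel)$taxon_ids),
                       rel)

  # a sample containing every network taxon reproduces the network
  full <- unclass(sim$otu)
  full[, 1] <- 1
  xfull <- otu_table(full, kingdom = otu_kingdom(sim$otu))
  sub <- sample_subnetwork(net, xfull, colnames(xfull)[1])
  expect_equal(sub$n_nodes, nrow(net$nodes))
  expect_equal(sub$n_edges, nrow(net$edges))

  # a sample with none gives the empty subnetwork, complexity 0
  none <- unclass(sim$otu)
  none[, 2] <- 0
  xnone <- otu_table(none, kingdom = otu_kingdom(sim$otu))
  sub0 <- sample_subnetwork(net, xnone, colnames(xnone)[2])
  expect_equal(sub0$n_nodes, 0)
  expect_equal(sub0$complexity, 0)

  # random presence pattern: induced edges equal a brute-force filter
  s <- colnames(sim$otu)[5]
  present <- rownames(sim$otu)[unclass(sim$otu)[, s] > 0]
  subr <- sample_subnetwork(net, sim$otu, s)
  manual <- net$edges[net$edges$taxon_a %in% present &
                        net$edges$taxon_b %in% present, ]
  expect_equal(subr$n_edges, nrow(manual))
  expect_error(sample_subnetwork(net, sim$otu, "nope"), "unknown sample")
})

test_that("adding a taxon to a sample never shrinks its subnetwork", {
  sim <- small_sim(seed = 53)
  rel <- to_relative(sim$otu)
  net <- build_network(spearman_all_pairs(rel, select_core(rel)$taxon_ids),
                       rel)
  m <- unclass(sim$otu)
  s <- NULL
  for (cand in colnames(m)) {
    if (any(m[net$nodes$taxon_id, cand] == 0)) { s <- cand; break }
  }
  expect_false(is.null(s))
  absent <- intersect(net$nodes$taxon_id, rownames(m)[m[, s] == 0])
  before <- sample_subnetwork(net, sim$otu, s)
  m[absent[1], s] <- 1
  after <- sample_subnetwork(net, otu_table(m, otu_kingdom(sim$otu)), s)
  expect_gte(after$n_nodes, before$n_nodes)
  expect_gte(after$n_edges, before$n_edges)
})

test_that("group comparisons detect extreme separation and not identity", {
  f <- data.frame(node = as.character(1:6), degree = c(1, 2, 3, 10, 11, 12))
  res <- compare_feature_groups(f, rep(c("a", "b"), each = 3))
  # most extreme rank assignment for n = 3, 3 under the normal approximation
  expect_lt(res$p[res$feature == "degree"], 0.1)

  fid <- data.frame(node = as.character(1:8), degree = rep(c(1, 2, 3, 4), 2))
  rid <- compare_feature_groups(fid, rep(c("a", "b"), each = 4))
  expect_gt(rid$p[rid$feature == "degree"], 0.9)
})
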