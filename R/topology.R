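#' Node-level topological features
#'
#' Degree, betweenness (exact shortest-path counting, unweighted), closeness
#' and eigenvector centrality for every node. Closeness uses a per-component
#' convention suited to the often-disconnected per-sample subnetworks:
#' `(n_c - 1) / sum(d_ij)` over the node's component (component size n_c),
#' 0 for isolated nodes, so values stay in [0, 1]. A harmonic variant
#' (`sum(1/d_ij) / (n - 1)` over all other nodes) is available by flag.
#' Eigenvector centrality is computed on the largest connected component and
#' set to 0 elsewhere, normalized to a maximum of 1.
#'
#' @param net a `cooc_network` or igraph graph (nonempty).
#' @param closeness `"component"` (default) or `"harmonic"`.
#' @return data.frame with `node`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`.
#' @export
node_features <- function(net, closeness = c("component", "harmonic")) {
  closeness <- match.arg(closeness)
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  stop_if_not(n > 0, "empty graph")
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  d <- igraph::distances(g, weights = NA)
  comp <- igraph::components(g)
  clo <- numeric(n)
  for (v in seq_len(n)) {
    if (closeness == "harmonic") {
      dv <- d[v, -v]
      clo[v] <- if (n > 1) sum(1 / dv[is.finite(dv)]) / (n - 1) else 0
    } else {
      members <- which(comp$membership == comp$membership[v])
      nc <- length(members)
      clo[v] <- if (nc > 1) (nc - 1) / sum(d[v, setdiff(members, v)]) else 0
    }
  }
  eig <- eigenvector_scores(g, comp)
  data.frame(node = nm, degree = unname(deg), betweenness = unname(btw),
             closeness = clo, eigenvector = eig, stringsAsFactors = FALSE)
}

# Deterministic eigenvector centrality: power iteration with a unit shift
# (A + I, which shares the Perron vector and cannot oscillate on bipartite
# components) on the largest connected component, zero elsewhere, scaled to
# max 1. Nodes in size-1 components (and edgeless graphs) score 0.
eigenvector_scores <- function(g, comp = igraph::components(g),
                               tol = 1e-13, max_iter = 10000L) {
  n <- igraph::vcount(g)
  eig <- numeric(n)
  big <- which(comp$membership == which.max(comp$csize))
  if (length(big) < 2) return(eig)
  a <- igraph::as_adjacency_matrix(igraph::induced_subgraph(g, big),
                                   sparse = FALSE)
  x <- rep(1, nrow(a))
  for (i in seq_len(max_iter)) {
    xn <- as.numeric(a %*% x) + x
    xn <- xn / max(xn)
    if (max(abs(xn - x)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  eig[big] <- x
  eig
}

#' Average shortest-path length
#'
#' Mean geodesic distance over all connected ordered pairs; disconnected
#' pairs are excluded rather than given an arbitrary length.
#'
#' @param net a `cooc_network` or igraph graph with >= 2 nodes.
#' @return Numeric; `NA` (with a warning) when no pair is connected.
#' @export
average_path_length <- function(net) {
  g <- as_igraph(net)
  stop_if_not(igraph::vcount(g) >= 2, "need >= 2 nodes")
  if (igraph::ecount(g) == 0) {
    warning("no connected pair; average path length undefined")
    return(NA_real_)
  }
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Network-level topological features
#'
#' The ten network-level features used to profile a co-occurrence network:
#' node and edge counts, average degree, average path length, density,
#' modularity (on the partition from [detect_modules()], re-detected here
#' with a fixed seed unless a partition is supplied), global clustering
#' coefficient (transitivity; average-local by flag), and Freeman
#' centralization of degree, betweenness, closeness and eigenvector
#' centrality, each normalized by its star-graph maximum. Centralizations
#' need at least 3 nodes and are `NA` below that.
#'
#' @param net a `cooc_network` or igraph graph.
#' @param partition optional `module_partition`; detected if missing.
#' @param clustering `"global"` (transitivity, default) or `"average_local"`.
#' @param seed seed forwarded to module detection.
#' @return Named list of the ten features.
#' @export
network_features <- function(net, partition = NULL,
                             clustering = c("global", "average_local"),
                             seed = 1) {
  clustering <- match.arg(clustering)
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  stop_if_not(n > 0, "empty graph")
  if (is.null(partition) && m > 0) partition <- detect_modules(g, seed = seed)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  mod <- if (m > 0) {
    igraph::modularity(g, membership = partition$membership[nm])
  } else NA_real_
  cc <- if (clustering == "global") {
    igraph::transitivity(g, type = "global")
  } else {
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  }
  if (is.nan(cc)) cc <- NA_real_
  apl <- if (n >= 2 && m > 0) average_path_length(g) else NA_real_
  if (n >= 3) {
    cd <- igraph::centr_degree(g, loops = FALSE, normalized = TRUE)$centralization
    cb <- igraph::centr_betw(g, directed = FALSE, normalized = TRUE)$centralization
    ev <- eigenvector_scores(g)
    ce <- sum(max(ev) - ev) / ((n - 1) * (1 - 1 / sqrt(n - 1)))
    cd <- min(max(cd, 0), 1)
    cb <- min(max(cb, 0), 1)
    ce <- min(max(ce, 0), 1)
  } else {
    cd <- cb <- ce <- NA_real_
  }
  list(n_nodes = n,
       n_edges = m,
       average_degree = if (n > 0) 2 * m / n else NA_real_,
       average_path_length = apl,
       density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_,
       modularity = mod,
       clustering_coefficient = cc,
       degree_centralization = cd,
       betweenness_centralization = cb,
       eigenvector_centralization = ce)
}

#' Edge-to-node complexity ratio
#'
#' The ratio of links to nodes, used as an abundance-free measure of network
#' complexity; defined as 0 for an empty graph.
#'
#' @param net a `cooc_network` or igraph graph.
#' @return Numeric ratio.
#' @export
complexity <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  igraph::ecount(g) / n
}

#' Per-sample induced subnetwork
#'
#' The subgraph induced on network nodes detected (abundance > 0) in one
#' sample, with its edge/node complexity.
#'
#' @param net a `cooc_network`.
#' @param x the `otu_table` (counts or relative) with that sample.
#' @param sample_id sample column name.
#' @return list with `sample_id`, `graph` (igraph), `n_nodes`, `n_edges`,
#'   `complexity`.
#' @export
sample_subnetwork <- function(net, x, sample_id) {
  stop_if_not(inherits(net, "cooc_network"), "net must be a cooc_network")
  stop_if_not(sample_id %in% colnames(x),
              paste0("unknown sample id: ", sample_id))
  present <- rownames(x)[unclass(x)[, sample_id] > 0]
  keep <- intersect(net$nodes$taxon_id, present)
  sub <- igraph::induced_subgraph(net$graph, keep)
  list(sample_id = sample_id, graph = sub,
       n_nodes = igraph::vcount(sub), n_edges = igraph::ecount(sub),
       complexity = complexity(sub))
}

#' Topology table over all per-sample subnetworks
#'
#' One row per sample: the ten network-level features of the induced
#' subnetwork plus its complexity and the six kingdom-by-sign edge counts.
#' This is the response table fed to the driver-attribution stage. Modules
#' are re-detected per subnetwork with a fixed seed.
#'
#' @param net a `cooc_network`.
#' @param x the `otu_table` with all samples.
#' @param seed seed for per-subnetwork module detection.
#' @return data.frame, one row per sample.
#' @export
per_sample_topology <- function(net, x, seed = 1) {
  rows <- lapply(colnames(x), function(s) {
    sub <- sample_subnetwork(net, x, s)
    g <- sub$graph
    feats <- if (igraph::vcount(g) > 0) {
      network_features(g, seed = seed)
    } else {
      setNames(as.list(c(0, 0, rep(NA_real_, 8))),
               c("n_nodes", "n_edges", "average_degree",
                 "average_path_length", "density", "modularity",
                 "clustering_coefficient", "degree_centralization",
                 "betweenness_centralization", "eigenvector_centralization"))
    }
    sg_edges <- igraph::as_data_frame(g, what = "edges")
    counts <- if (nrow(sg_edges)) {
      edge_partition_counts(data.frame(kind = sg_edges$kind,
                                       sign = sg_edges$sign))
    } else {
      edge_partition_counts(data.frame(kind = character(),
                                       sign = character()))
    }
    c(list(sample_id = s), feats, list(complexity = sub$complexity),
      as.list(counts))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Compare node features between groups
#'
#' Two-sided Wilcoxon rank-sum tests per feature for every pair of groups
#' (e.g. bacteria vs fungi, or high- vs low-pH cluster).
#'
#' @param features data.frame from [node_features()].
#' @param labels group label per node (same order as `features`).
#' @return data.frame with `feature`, `group_a`, `group_b`, `statistic`, `p`.
#' @export
compare_feature_groups <- function(features, labels) {
  stop_if_not(length(labels) == nrow(features),
              "labels must match feature rows")
  groups <- unique(labels)
  stop_if_not(length(groups) >= 2, "need >= 2 groups")
  stop_if_not(all(table(labels) >= 1), "empty group")
  feats <- setdiff(names(features), "node")
  out <- list()
  for (f in feats) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq((i + 1), length(groups))) {
        a <- features[[f]][labels == groups[i]]
        b <- features[[f]][labels == groups[j]]
        wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
        out[[length(out) + 1]] <- data.frame(
          feature = f, group_a = groups[i], group_b = groups[j],
          statistic = unname(wt$statistic), p = wt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
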