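#' Natural connectivity of a graph
#'
#' The log of the average exponentiated adjacency eigenvalue,
#' `ln((1/N) * sum_i exp(lambda_i))`: a spectral measure of the redundancy
#' of closed walks that degrades smoothly as a network loses nodes, used
#' here as the robustness statistic. Isolated nodes stay in N (each
#' contributes exp(0)), keeping the statistic size-normalized. Computed by
#' dense symmetric eigendecomposition with a log-sum-exp guard, adequate for
#' networks of a few thousand nodes.
#'
#' @param net a `cooc_network` or igraph graph with >= 1 node.
#' @return Numeric; 0 for an edgeless graph, `NA` (flag) for an empty graph.
#' @export
natural_connectivity <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) {
    warning("empty graph: natural connectivity undefined")
    return(NA_real_)
  }
  if (igraph::ecount(g) == 0) return(0)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  log_mean_exp(ev)
}

#' Natural-connectivity robustness curve under random node removal
#'
#' For each removal fraction f, `floor(f * N)` nodes are removed uniformly
#' at random (independently per replicate) and natural connectivity of the
#' remaining graph is recorded; the curve reports mean and sd over
#' replicates. Fraction 0 reproduces the intact value with sd 0.
#'
#' @param net a `cooc_network` or igraph graph.
#' @param fractions removal fractions, sorted, in [0, 1).
#' @param n_reps replicates per fraction (>= 1).
#' @param seed integer seed.
#' @return Object of class `robustness_curve`: data.frame with `fraction`,
#'   `mean`, `sd`, plus attributes `n_reps` and `seed`.
#' @export
robustness_curve <- function(net, fractions = seq(0, 0.8, by = 0.05),
                             n_reps = 100, seed = 1) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  stop_if_not(n >= 1, "empty graph")
  stop_if_not(all(fractions >= 0 & fractions < 1),
              "fractions must lie in [0, 1)")
  stop_if_not(!is.unsorted(fractions), "fractions must be sorted")
  stop_if_not(n_reps >= 1, "n_reps must be >= 1")
  stop_if_not(all(floor(fractions * n) < n), "a fraction removes all nodes")
  base_nc <- natural_connectivity(g)
  out <- with_seed(seed, {
    mns <- sds <- numeric(length(fractions))
    for (i in seq_along(fractions)) {
      n_rm <- floor(fractions[i] * n)
      if (n_rm == 0) {
        mns[i] <- base_nc
        sds[i] <- 0
        next
      }
      vals <- vapply(seq_len(n_reps), function(r) {
        keep <- setdiff(seq_len(n), sample.int(n, n_rm))
        natural_connectivity(igraph::induced_subgraph(g, keep))
      }, numeric(1))
      mns[i] <- mean(vals)
      sds[i] <- if (n_reps > 1) sd(vals) else 0
    }
    data.frame(fraction = fractions, mean = mns, sd = sds)
  })
  structure(out, n_reps = n_reps, seed = seed,
            class = c("robustness_curve", "data.frame"))
}

#' @export
plot.robustness_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    plot(x$fraction, x$mean, type = "l", col = col,
         xlab = "fraction of nodes removed",
         ylab = "natural connectivity", ...)
  } else {
    graphics::lines(x$fraction, x$mean, col = col, ...)
  }
  graphics::arrows(x$fraction, x$mean - x$sd, x$fraction, x$mean + x$sd,
                   angle = 90, code = 3, length = 0.02, col = col)
  invisible(x)
}

#' Robustness curves for ecological-cluster subnetworks
#'
#' Induces the subgraph on each cluster's nodes (e.g. the high- and low-pH
#' ecological clusters) and computes a robustness curve per cluster, the
#' comparison used to ask which cluster's network is more stable.
#'
#' @param net a `cooc_network`.
#' @param clusters named vector: cluster label per taxon id (labels other
#'   than the two of interest, e.g. `"other"`, may be dropped beforehand).
#' @param fractions,n_reps,seed forwarded to [robustness_curve()].
#' @return Named list of `robustness_curve` objects, one per cluster label.
#' @export
compare_cluster_robustness <- function(net, clusters,
                                       fractions = seq(0, 0.8, by = 0.05),
                                       n_reps = 100, seed = 1) {
  stop_if_not(inherits(net, "cooc_network"), "net must be a cooc_network")
  labs <- unique(clusters)
  out <- list()
  for (i in seq_along(labs)) {
    ids <- intersect(names(clusters)[clusters == labs[i]],
                     net$nodes$taxon_id)
    stop_if_not(length(ids) > 0, paste0("empty cluster: ", labs[i]))
    sub <- igraph::induced_subgraph(net$graph, ids)
    out[[labs[i]]] <- robustness_curve(sub, fractions, n_reps,
                                       seed = derive_seed(seed, i))
  }
  out
}
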