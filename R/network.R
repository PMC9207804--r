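#' All-pairs Spearman correlation with BH-adjusted p-values
#'
#' Computes Spearman's rho on mid-ranks (average ranks for ties) for every
#' unordered pair of taxa, a two-sided p-value from the t approximation with
#' n - 2 degrees of freedom, and Benjamini-Hochberg q-values over all
#' C(n_taxa, 2) pairs. Taxa with constant abundance across samples have no
#' defined rank correlation; their pairs are recorded as rho = 0, p = 1 and
#' flagged rather than erroring, so degenerate taxa cannot crash a run.
#'
#' @param x an `otu_table` (relative abundances recommended); taxa are the
#'   variables, samples the observations.
#' @param taxa optional character vector restricting to a taxon subset
#'   (e.g. the core set).
#' @return Object of class `cooc_cor`: list with symmetric matrices `rho`,
#'   `p`, `q` (NA diagonal), `n_samples`, and `constant` (ids of flagged
#'   constant taxa).
#' @export
spearman_all_pairs <- function(x, taxa = NULL) {
  stop_if_not(inherits(x, "otu_table"), "x must be an otu_table")
  if (!is.null(taxa)) x <- x[taxa, , drop = FALSE]
  m <- unclass(x)
  stop_if_not(ncol(m) >= 3, "need at least 3 samples")
  stop_if_not(nrow(m) >= 2, "need at least 2 taxa")
  n <- ncol(m)
  ranks <- t(apply(m, 1, rank))           # mid-ranks
  const <- apply(m, 1, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(cor(t(ranks)))  # Pearson on ranks = Spearman
  rho[const, ] <- 0
  rho[, const] <- 0
  rho <- pmin(pmax(rho, -1), 1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p[const, ] <- 1
  p[, const] <- 1
  diag(rho) <- NA
  diag(p) <- NA
  q <- p
  lt <- lower.tri(p)
  q[lt] <- p.adjust(p[lt], method = "BH")
  q <- pmin(q, 1)
  q[upper.tri(q)] <- t(q)[upper.tri(q)]
  structure(list(rho = rho, p = p, q = q, n_samples = n,
                 constant = rownames(m)[const]),
            class = "cooc_cor")
}

#' @export
print.cooc_cor <- function(x, ...) {
  cat(sprintf("Spearman correlation over %d taxa, %d samples (%d pairs)\n",
              nrow(x$rho), x$n_samples, choose(nrow(x$rho), 2)))
  if (length(x$constant)) {
    cat("  constant (flagged) taxa:", length(x$constant), "\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as the
#' package's single named FDR entry point.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Build the thresholded, signed co-occurrence network
#'
#' An edge connects two taxa when the correlation is strong
#' (`|rho| > rho_min` by default, `rho > rho_min` with `use_abs = FALSE`)
#' and significant after FDR correction (`q < q_max`); both comparisons are
#' strict, so boundary values produce no edge. Core taxa with no retained
#' edge are dropped from the node set. Each edge carries `rho`, `q`, a
#' `sign` (`"positive"` iff rho > 0), and a `kind` label by kingdom pair
#' (`"BB"`, `"BF"`, `"FF"`).
#'
#' @param corr a `cooc_cor` from [spearman_all_pairs()].
#' @param x the `otu_table` the correlations came from (for kingdom and mean
#'   relative abundance node annotation).
#' @param rho_min correlation threshold (strict).
#' @param q_max FDR threshold (strict).
#' @param use_abs threshold on `|rho|` (default TRUE), so strong negative
#'   associations form (red) edges too.
#' @return Object of class `cooc_network`: list with `graph` (igraph),
#'   `nodes` (data.frame: `taxon_id`, `kingdom`, `mean_rel_abund`), `edges`
#'   (data.frame: `taxon_a`, `taxon_b`, `rho`, `q`, `sign`, `kind`),
#'   `summary` (named counts), and the thresholds used.
#' @export
build_network <- function(corr, x, rho_min = 0.6, q_max = 0.01,
                          use_abs = TRUE) {
  stop_if_not(inherits(corr, "cooc_cor"), "corr must be a cooc_cor")
  stop_if_not(rho_min >= 0 && rho_min <= 1, "rho_min must be in [0, 1]")
  stop_if_not(q_max > 0 && q_max <= 1, "q_max must be in (0, 1]")
  ids <- rownames(corr$rho)
  strength <- if (use_abs) abs(corr$rho) else corr$rho
  keep <- lower.tri(corr$rho) & strength > rho_min & corr$q < q_max
  keep[is.na(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  # lower triangle: row index > col index; order the pair by taxon id
  a <- ids[idx[, "col"]]
  b <- ids[idx[, "row"]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  rho <- corr$rho[idx]
  q <- corr$q[idx]
  kingdom <- otu_kingdom(x)
  rel <- to_relative(x)
  kind <- edge_kind(kingdom[a], kingdom[b])
  edges <- data.frame(taxon_a = a, taxon_b = b, rho = rho, q = q,
                      sign = ifelse(rho > 0, "positive", "negative"),
                      kind = kind, stringsAsFactors = FALSE)
  edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  nodes <- data.frame(taxon_id = node_ids,
                      kingdom = unname(kingdom[node_ids]),
                      mean_rel_abund = unname(rowMeans(rel)[node_ids]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new_cooc_network(g, nodes, edges, rho_min = rho_min, q_max = q_max,
                   use_abs = use_abs)
}

edge_kind <- function(ka, kb) {
  ifelse(ka == "bacteria" & kb == "bacteria", "BB",
         ifelse(ka == "fungi" & kb == "fungi", "FF", "BF"))
}

new_cooc_network <- function(g, nodes, edges, ...) {
  smry <- c(n_nodes = nrow(nodes), n_edges = nrow(edges),
            positive = sum(edges$sign == "positive"),
            negative = sum(edges$sign == "negative"),
            edge_partition_counts(edges))
  structure(list(graph = g, nodes = nodes, edges = edges, summary = smry,
                 params = list(...)),
            class = "cooc_network")
}

edge_partition_counts <- function(edges) {
  out <- setNames(integer(6),
                  c("BB_pos", "BB_neg", "BF_pos", "BF_neg", "FF_pos", "FF_neg"))
  if (nrow(edges)) {
    key <- paste0(edges$kind, ifelse(edges$sign == "positive", "_pos", "_neg"))
    tab <- table(key)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Partition the edge set by kingdom pair and sign
#'
#' @param net a `cooc_network`.
#' @return Named integer vector `BB_pos`, `BB_neg`, `BF_pos`, `BF_neg`,
#'   `FF_pos`, `FF_neg`; sums to the edge count.
#' @export
edge_partition <- function(net) {
  stop_if_not(inherits(net, "cooc_network"), "net must be a cooc_network")
  stop_if_not(!anyNA(net$nodes$kingdom), "missing kingdom label")
  edge_partition_counts(net$edges)
}

#' @export
print.cooc_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Co-occurrence network: %d nodes, %d edges\n",
              s["n_nodes"], s["n_edges"]))
  if (s["n_edges"] > 0) {
    cat(sprintf("  positive %d (%.1f%%), negative %d (%.1f%%)\n",
                s["positive"], 100 * s["positive"] / s["n_edges"],
                s["negative"], 100 * s["negative"] / s["n_edges"]))
    cat(sprintf("  BB %d | BF %d | FF %d\n",
                s["BB_pos"] + s["BB_neg"], s["BF_pos"] + s["BF_neg"],
                s["FF_pos"] + s["FF_neg"]))
  }
  invisible(x)
}

#' @export
summary.cooc_network <- function(object, ...) {
  top <- network_features(object)
  out <- list(summary = object$summary, topology = top,
              params = object$params)
  class(out) <- "summary.cooc_network"
  out
}

#' @export
print.summary.cooc_network <- function(x, ...) {
  print(structure(list(summary = x$summary), class = "cooc_network",
                  nodes = NULL))
  cat("Network-level topology:\n")
  print(unlist(x$topology))
  invisible(x)
}

#' @export
plot.cooc_network <- function(x, ...) {
  col <- ifelse(x$edges$sign == "negative", "red", "grey60")
  vcol <- ifelse(x$nodes$kingdom == "fungi", "goldenrod", "steelblue")
  igraph::plot.igraph(x$graph, edge.color = col, vertex.color = vcol,
                      vertex.size = 4, vertex.label = NA, ...)
  invisible(x)
}

#' Fit a power law to the degree distribution and compare with random graphs
#'
#' Least-squares fit of log P(k) against log k over observed positive
#' degrees, the conventional scale-free check, plus the mean clustering
#' coefficient and average path length of degree- and size-matched
#' Erdos-Renyi G(n, m) graphs as a random-graph reference.
#'
#' @param net a `cooc_network` or igraph graph with >= 1 edge.
#' @param n_random number of random reference graphs.
#' @param seed integer seed for the reference graphs.
#' @return list with `exponent`, `r2`, `flagged` (TRUE when fewer than two
#'   distinct positive degrees make the fit undefined), `er_clustering`,
#'   `er_avg_path_length`, `n_random`.
#' @export
scale_free_check <- function(net, n_random = 100, seed = 1) {
  g <- as_igraph(net)
  stop_if_not(igraph::ecount(g) >= 1, "network has no edges")
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(deg)
  flagged <- length(k) < 2
  exponent <- NA_real_
  r2 <- NA_real_
  if (!flagged) {
    fit <- lm(log(pk) ~ log(k))
    exponent <- unname(coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  ref <- with_seed(seed, {
    cc <- numeric(n_random)
    apl <- numeric(n_random)
    for (i in seq_len(n_random)) {
      er <- igraph::sample_gnm(n, m)
      cc[i] <- igraph::transitivity(er, type = "global")
      apl[i] <- igraph::mean_distance(er, directed = FALSE)
    }
    c(clustering = mean(cc, na.rm = TRUE), apl = mean(apl, na.rm = TRUE))
  })
  list(exponent = exponent, r2 = r2, flagged = flagged,
       er_clustering = unname(ref["clustering"]),
       er_avg_path_length = unname(ref["apl"]), n_random = n_random)
}

# Accept either a cooc_network or a bare igraph everywhere downstream.
as_igraph <- function(x) {
  if (inherits(x, "cooc_network")) return(x$graph)
  stop_if_not(igraph::is_igraph(x), "expected a cooc_network or igraph graph")
  x
}

#' Write a network to GraphML or a tab-separated edge list
#'
#' Both formats round-trip the node set, edge set, and the `rho`, `q`,
#' `sign` edge attributes through [read_network()].
#'
#' @param net a `cooc_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"edge_list"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_list")) {
  format <- match.arg(format)
  stop_if_not(inherits(net, "cooc_network"), "net must be a cooc_network")
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    hdr <- net$edges
    write_tsv(hdr, path)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge_list"`.
#' @param nodes optional node data.frame (`taxon_id`, `kingdom`,
#'   `mean_rel_abund`) for the edge-list format, which stores only edges
#'   (isolated nodes cannot be recovered from it).
#' @return A `cooc_network`.
#' @export
read_network <- function(path, format = c("graphml", "edge_list"),
                         nodes = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(taxon_id = igraph::V(g)$name,
                        kingdom = igraph::V(g)$kingdom,
                        mean_rel_abund = igraph::V(g)$mean_rel_abund,
                        stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(taxon_a = pmin(el$from, el$to),
                        taxon_b = pmax(el$from, el$to),
                        rho = el$rho, q = el$q, sign = el$sign,
                        kind = el$kind, stringsAsFactors = FALSE)
  } else {
    edges <- read.delim(path, header = TRUE, comment.char = "#",
                        stringsAsFactors = FALSE)
    if (is.null(nodes)) {
      ids <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
      nodes <- data.frame(taxon_id = ids, kingdom = NA_character_,
                          mean_rel_abund = NA_real_, stringsAsFactors = FALSE)
    }
  }
  edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  new_cooc_network(g, nodes, edges)
}
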