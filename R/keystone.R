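#' Detect network modules
#'
#' Community detection used both for modularity and for the Zi-Pi node-role
#' analysis. `"greedy"` (default) is fast greedy modularity maximization;
#' `"louvain"` is multilevel modularity optimization; `"markov_flow"` is a
#' flow-based clustering of MCL type (repeated expansion and inflation of
#' the column-normalized adjacency with self-loops), provided for fidelity
#' with pipelines built on Markov clustering. All methods are deterministic
#' for a given seed, and isolated nodes become singleton modules.
#'
#' @param net a `cooc_network` or igraph graph (nonempty).
#' @param method `"greedy"`, `"louvain"`, or `"markov_flow"`.
#' @param seed integer seed (stochastic tie-breaking in louvain).
#' @param inflation MCL inflation exponent (markov_flow only).
#' @return Object of class `module_partition`: list with `membership`
#'   (named integer vector), `method`, `seed`, `n_modules`.
#' @export
detect_modules <- function(net, method = c("greedy", "louvain", "markov_flow"),
                           seed = 1, inflation = 2) {
  method <- match.arg(method)
  g <- as_igraph(net)
  stop_if_not(igraph::vcount(g) > 0, "empty network")
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  membership <- with_seed(seed, {
    if (method == "greedy") {
      if (igraph::ecount(g) == 0) {
        seq_len(igraph::vcount(g))
      } else {
        igraph::membership(igraph::cluster_fast_greedy(g, weights = NULL))
      }
    } else if (method == "louvain") {
      igraph::membership(igraph::cluster_louvain(g, weights = NULL))
    } else {
      mcl_membership(g, inflation = inflation)
    }
  })
  membership <- setNames(as.integer(membership), nm)
  structure(list(membership = membership, method = method, seed = seed,
                 n_modules = length(unique(membership))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition (%s): %d modules over %d nodes\n",
              x$method, x$n_modules, length(x$membership)))
  invisible(x)
}

# MCL-style flow clustering: column-stochastic adjacency with self-loops,
# alternate expansion (M %*% M) and inflation (entrywise power, renormalize),
# prune tiny entries, read clusters off the attractor rows.
mcl_membership <- function(g, inflation = 2, max_iter = 100, tol = 1e-8,
                           prune = 1e-6) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(a)
  diag(a) <- 1
  m <- sweep(a, 2, colSums(a), "/")
  for (i in seq_len(max_iter)) {
    m2 <- m %*% m
    m2 <- m2^inflation
    m2[m2 < prune] <- 0
    cs <- colSums(m2)
    cs[cs == 0] <- 1
    m2 <- sweep(m2, 2, cs, "/")
    if (max(abs(m2 - m)) < tol) {
      m <- m2
      break
    }
    m <- m2
  }
  attractors <- which(rowSums(m) > tol)
  membership <- rep(NA_integer_, n)
  mod <- 0L
  for (r in attractors) {
    members <- which(m[r, ] > tol)
    hit <- membership[members]
    if (any(!is.na(hit))) {
      membership[members] <- hit[!is.na(hit)][1]
    } else {
      mod <- mod + 1L
      membership[members] <- mod
    }
  }
  for (v in which(is.na(membership))) {
    mod <- mod + 1L
    membership[v] <- mod
  }
  membership
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For node i in module s, `Zi = (k_i_own - mean_own) / sd_own`, the z-score
#' of its within-module degree against its module's members (population sd);
#' `Pi = 1 - sum_s (k_is / k_i)^2`, the participation coefficient over the
#' modules its edges reach. Degenerate conventions: a module whose members
#' all have the same within-module degree gives Zi = 0 for all of them, and
#' an isolated node (k_i = 0) gets Pi = 0.
#'
#' @param net a `cooc_network` or igraph graph.
#' @param partition a `module_partition` covering the network (detected with
#'   defaults if missing).
#' @return data.frame with `node`, `module`, `degree`, `within_degree`,
#'   `Zi`, `Pi`.
#' @export
zi_pi <- function(net, partition = NULL) {
  g <- as_igraph(net)
  if (is.null(partition)) partition <- detect_modules(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  stop_if_not(all(nm %in% names(partition$membership)),
              "partition does not cover the network")
  mem <- partition$membership[nm]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- length(nm)
  k <- igraph::degree(g)
  # k_is: links from node i into module s
  mods <- sort(unique(mem))
  kis <- matrix(0, n, length(mods), dimnames = list(nm, as.character(mods)))
  for (s in seq_along(mods)) {
    cols <- which(mem == mods[s])
    kis[, s] <- if (length(cols)) rowSums(adj[, cols, drop = FALSE]) else 0
  }
  k_own <- kis[cbind(seq_len(n), match(mem, mods))]
  zi <- numeric(n)
  for (s in mods) {
    members <- which(mem == s)
    ks <- k_own[members]
    mu <- mean(ks)
    sdev <- sqrt(mean((ks - mu)^2))   # population sd
    zi[members] <- if (sdev > 0) (ks - mu) / sdev else 0
  }
  pi <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, 1))^2), 0)
  data.frame(node = nm, module = as.integer(mem), degree = unname(k),
             within_degree = unname(k_own), Zi = zi, Pi = unname(pi),
             stringsAsFactors = FALSE)
}

#' Classify node roles in Zi-Pi space
#'
#' Four-way classification at the conventional thresholds Zi = 2.5 and
#' Pi = 0.62, with boundary values (<=) assigned to the lower category:
#' peripherals (Zi <= 2.5, Pi <= 0.62), connectors (Zi <= 2.5, Pi > 0.62),
#' module hubs (Zi > 2.5, Pi <= 0.62) and network hubs (Zi > 2.5,
#' Pi > 0.62). Connectors and both hub types are flagged as putative
#' keystone taxa.
#'
#' @param roles data.frame from [zi_pi()].
#' @param zi_threshold,pi_threshold classification thresholds.
#' @return The input with `role` and logical `keystone` columns added.
#' @export
classify_roles <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  stop_if_not(all(c("Zi", "Pi") %in% names(roles)),
              "roles must contain Zi and Pi")
  hi_z <- roles$Zi > zi_threshold
  hi_p <- roles$Pi > pi_threshold
  roles$role <- ifelse(hi_z & hi_p, "network_hub",
                       ifelse(hi_z, "module_hub",
                              ifelse(hi_p, "connector", "peripheral")))
  roles$keystone <- roles$role != "peripheral"
  roles
}

#' Environmental profile of keystone taxa
#'
#' For each keystone taxon: Spearman correlation (rho, p) of its relative
#' abundance with every environmental variable, and the per-variable
#' explained-variance share from a multiple regression on distance matrices
#' of its abundance profile against the per-variable environment distances.
#'
#' @param keystone_ids character vector of keystone taxon ids (nonempty).
#' @param x `otu_table` containing them.
#' @param env environment data.frame (`sample_id` + numeric variables).
#' @param n_perm permutations for the MRM p-values.
#' @param seed integer seed.
#' @return list with matrices `rho`, `p`, `share` (taxa x variables).
#' @export
keystone_env_profile <- function(keystone_ids, x, env, n_perm = 99,
                                 seed = 1) {
  stop_if_not(length(keystone_ids) > 0, "empty keystone set")
  stop_if_not(all(keystone_ids %in% rownames(x)),
              "keystone ids missing from the table")
  rel <- to_relative(x)
  vars <- setdiff(names(env), "sample_id")
  rho <- p <- share <- matrix(NA_real_, length(keystone_ids), length(vars),
                              dimnames = list(keystone_ids, vars))
  pred <- lapply(vars, function(v) env_distance(env, v))
  names(pred) <- vars
  for (i in seq_along(keystone_ids)) {
    ab <- unclass(rel)[keystone_ids[i], ]
    for (j in seq_along(vars)) {
      ct <- spearman_rho_p(ab, env[[vars[j]]])
      rho[i, j] <- ct$rho
      p[i, j] <- ct$p
    }
    resp <- dist_matrix(as.matrix(dist(ab)), env$sample_id, "euclidean")
    fit <- mrm(resp, pred, n_perm = n_perm, seed = derive_seed(seed, i))
    share[i, ] <- fit$share[vars]
  }
  list(rho = rho, p = p, share = share)
}

# Spearman rho and two-sided t-approximation p for a single pair.
spearman_rho_p <- function(x, y) {
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = 0, p = 1, flagged = TRUE))
  }
  n <- length(x)
  r <- cor(rank(x), rank(y))
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(list(rho = r, p = 0, flagged = FALSE))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tt), df = n - 2), flagged = FALSE)
}
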