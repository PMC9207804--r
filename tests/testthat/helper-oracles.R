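# Independent brute-force oracles, deliberately written against plain
# matrices/loops rather than the package's own code paths or igraph metrics.

# Spearman via explicit ranks then textbook Pearson on the rank vectors.
oracle_spearman <- function(m) {
  nt <- nrow(m)
  r <- matrix(NA_real_, nt, nt, dimnames = list(rownames(m), rownames(m)))
  rk <- t(apply(m, 1, rank))
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      x <- rk[i, ]; y <- rk[j, ]
      sx <- sqrt(sum((x - mean(x))^2))
      sy <- sqrt(sum((y - mean(y))^2))
      r[i, j] <- if (sx == 0 || sy == 0) 0 else
        sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
    }
  }
  r
}

# BH step-up by hand: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Double loop applying both thresholds to rho/q matrices.
oracle_edges <- function(rho, q, rho_min, q_max, use_abs = TRUE) {
  ids <- rownames(rho)
  out <- list()
  for (i in seq_len(nrow(rho) - 1)) {
    for (j in seq((i + 1), nrow(rho))) {
      s <- if (use_abs) abs(rho[i, j]) else rho[i, j]
      if (!is.na(s) && s > rho_min && q[i, j] < q_max) {
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        out[[length(out) + 1]] <- data.frame(taxon_a = a, taxon_b = b,
                                             rho = rho[i, j], q = q[i, j])
      }
    }
  }
  if (!length(out)) return(data.frame(taxon_a = character(),
                                      taxon_b = character(),
                                      rho = numeric(), q = numeric()))
  df <- do.call(rbind, out)
  df[order(df$taxon_a, df$taxon_b), , drop = FALSE]
}

# All-pairs BFS distances from an adjacency matrix.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        nbr <- which(adj[v, ] > 0)
        new <- nbr[d[s, nbr] == Inf & nbr != s]
        d[s, new] <- dist
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Shortest-path counts sigma[s, t] via BFS layer DP from every source.
oracle_sigma <- function(adj, d) {
  n <- nrow(adj)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    reach <- which(is.finite(d[s, ]) & d[s, ] > 0)
    for (t in reach[order(d[s, reach])]) {
      preds <- which(adj[t, ] > 0 & d[s, ] == d[s, t] - 1)
      sig[s, t] <- sum(sig[s, preds])
    }
  }
  sig
}

# Betweenness: sum over pairs s < t of the fraction of s-t geodesics
# passing through v.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sig <- oracle_sigma(adj, d)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(d[s, t]) || sig[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  btw
}

# Per-component closeness from the BFS distance matrix.
oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    members <- which(is.finite(d[v, ]))
    nc <- length(members)
    if (nc <= 1) return(0)
    (nc - 1) / sum(d[v, setdiff(members, v)])
  }, numeric(1))
}

# Eigenvector centrality: dense eigen-solve on the largest component.
oracle_eigenvector <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  comp_of <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp_of[v])) {
      cid <- cid + 1
      comp_of[is.finite(d[v, ])] <- cid
    }
  }
  sizes <- table(comp_of)
  big <- which(comp_of == as.integer(names(sizes)[which.max(sizes)]))
  out <- numeric(n)
  if (length(big) == 1) {
    out[big] <- 1
    return(out)
  }
  sub <- adj[big, big]
  es <- eigen(sub, symmetric = TRUE)
  v1 <- abs(es$vectors[, 1])
  out[big] <- v1 / max(v1)
  out
}

# Zi/Pi by per-node tallies over an explicit edge loop.
oracle_zipi <- function(adj, membership) {
  n <- nrow(adj)
  mods <- sort(unique(membership))
  kis <- matrix(0, n, length(mods))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j] > 0) {
        s <- match(membership[j], mods)
        kis[i, s] <- kis[i, s] + 1
      }
    }
  }
  k <- rowSums(kis)
  zi <- numeric(n)
  for (s in mods) {
    mem <- which(membership == s)
    kown <- vapply(mem, function(i) kis[i, match(s, mods)], numeric(1))
    mu <- mean(kown)
    sdev <- sqrt(sum((kown - mu)^2) / length(kown))
    zi[mem] <- if (sdev > 0) (kown - mu) / sdev else 0
  }
  pi <- vapply(seq_len(n), function(i) {
    if (k[i] == 0) return(0)
    1 - sum((kis[i, ] / k[i])^2)
  }, numeric(1))
  list(Zi = zi, Pi = pi)
}

# Natural connectivity via the power series for tr(exp(A)).
oracle_natural_connectivity <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(NA_real_)
  term <- diag(n)
  s <- n   # tr(I)
  for (k in 1:250) {
    term <- term %*% adj / k
    s <- s + sum(diag(term))
  }
  log(s / n)
}

# Random simple undirected graph as a plain adjacency matrix.
random_adj <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
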