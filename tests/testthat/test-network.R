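test_that("spearman engine handles monotone, reversed and constant taxa", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1), d = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  x <- otu_table(m)
  res <- spearman_all_pairs(x)
  expect_equal(res$rho["a", "b"], 1)
  expect_equal(res$rho["a", "c"], -1)
  expect_equal(res$rho["a", "d"], 0)
  expect_equal(res$p["a", "d"], 1)
  expect_identical(res$constant, "d")
})

test_that("spearman matrix matches the rank-then-Pearson oracle", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rpois(10 * 20, 5), nrow = 10,
                dimnames = list(sprintf("t%02d", 1:10), paste0("s", 1:20)))
    x <- otu_table(m)
    res <- spearman_all_pairs(x)
    o <- oracle_spearman(m)
    expect_equal(res$rho, o, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand step-up and is permutation-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  set.seed(4)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-15)
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("edge thresholds are strict and negatives are representable", {
  # craft a correlation result with an exact-boundary rho
  rho <- matrix(c(NA, 0.6, -0.9,
                  0.6, NA, 0.2,
                  -0.9, 0.2, NA), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  q <- matrix(0.001, 3, 3, dimnames = dimnames(rho))
  diag(q) <- NA
  corr <- structure(list(rho = rho, p = q, q = q, n_samples = 30,
                         constant = character(0)), class = "cooc_cor")
  x <- otu_table(matrix(1:9, 3, dimnames = list(c("a", "b", "c"),
                                                paste0("s", 1:3))))
  net <- build_network(corr, x, rho_min = 0.6, q_max = 0.01, use_abs = TRUE)
  expect_equal(nrow(net$edges), 1)       # the 0.6 edge is excluded
  expect_equal(net$edges$sign, "negative")
  expect_equal(net$edges$rho, -0.9)

  net2 <- build_network(corr, x, rho_min = 0.6, q_max = 0.01, use_abs = FALSE)
  expect_equal(nrow(net2$edges), 0)      # no positive rho above 0.6
})

test_that("network edge set matches the brute-force double loop", {
  for (s in 1:5) {
    sim <- small_sim(seed = 100 + s, n_samples = 25, n_bacteria = 10,
                     n_fungi = 2, n_guilds = 2)
    rel <- to_relative(sim$otu)
    corr <- spearman_all_pairs(rel)
    net <- build_network(corr, rel, rho_min = 0.3, q_max = 0.1)
    o <- oracle_edges(corr$rho, corr$q, 0.3, 0.1)
    expect_equal(nrow(net$edges), nrow(o))
    if (nrow(o)) {
      expect_equal(net$edges$taxon_a, o$taxon_a)
      expect_equal(net$edges$taxon_b, o$taxon_b)
      expect_equal(net$edges$rho, o$rho, tolerance = 1e-12)
    }
  }
})

test_that("threshold monotonicity: loosening thresholds never removes edges", {
  sim <- small_sim(seed = 41)
  rel <- to_relative(sim$otu)
  corr <- spearman_all_pairs(rel, select_core(rel)$taxon_ids)
  tight <- build_network(corr, rel, rho_min = 0.7, q_max = 0.005)
  loose <- build_network(corr, rel, rho_min = 0.6, q_max = 0.01)
  key <- function(n) paste(n$edges$taxon_a, n$edges$taxon_b)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("edge partition counts are consistent and match a recount", {
  sim <- small_sim(seed = 43)
  rel <- to_relative(sim$otu)
  net <- build_network(spearman_all_pairs(rel, select_core(rel)$taxon_ids),
                       rel)
  part <- edge_partition(net)
  expect_equal(sum(part), nrow(net$edges))
  kingdom <- otu_kingdom(rel)
  recount <- setNames(integer(6), names(part))
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    ks <- sort(c(kingdom[e$taxon_a], kingdom[e$taxon_b]))
    kind <- if (all(ks == "bacteria")) "BB" else
      if (all(ks == "fungi")) "FF" else "BF"
    key <- paste0(kind, if (e$sign == "positive") "_pos" else "_neg")
    recount[key] <- recount[key] + 1L
  }
  expect_equal(part, recount)

  # single cross-kingdom positive edge
  rho <- matrix(c(NA, 0.9, 0.9, NA), 2,
                dimnames = list(c("B1", "F1"), c("B1", "F1")))
  q <- matrix(1e-5, 2, 2, dimnames = dimnames(rho)); diag(q) <- NA
  corr <- structure(list(rho = rho, p = q, q = q, n_samples = 30,
                         constant = character(0)), class = "cooc_cor")
  x <- otu_table(matrix(1:6, 2, dimnames = list(c("B1", "F1"),
                                                paste0("s", 1:3))),
                 kingdom = c("bacteria", "fungi"))
  p1 <- edge_partition(build_network(corr, x))
  expect_equal(unname(p1["BF_pos"]), 1L)
  expect_equal(sum(p1), 1L)
})

test_that("a constructed power-law degree sequence is recovered exactly", {
  # counts proportional to k^-2 over k in {1,2,4,8}: 64, 16, 4, 1 nodes
  degs <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
  g <- igraph::realize_degseq(degs)
  igraph::V(g)$name <- sprintf("v%02d", seq_along(degs))
  net <- list(graph = g)
  class(net) <- "cooc_network"
  sf <- scale_free_check(net, n_random = 5, seed = 1)
  expect_false(sf$flagged)
  expect_equal(sf$exponent, -2, tolerance = 1e-6)
  expect_equal(sf$r2, 1, tolerance = 1e-9)
})

test_that("single-degree graphs are flagged; ER reference matches expectation", {
  k5 <- igraph::make_full_graph(5)
  expect_true(scale_free_check(k5, n_random = 3, seed = 1)$flagged)

  sf <- scale_free_check(igraph::sample_gnm(100, 300), n_random = 200,
                         seed = 7)
  expect_equal(sf$er_clustering, 600 / (100 * 99), tolerance = 0.02)
})

test_that("relabeling taxa permutes but does not change the edge set", {
  sim <- small_sim(seed = 47, n_samples = 25, n_bacteria = 12, n_fungi = 3)
  rel <- to_relative(sim$otu)
  corr <- spearman_all_pairs(rel)
  net <- build_network(corr, rel, rho_min = 0.4, q_max = 0.1)

  set.seed(99)
  perm <- sample(nrow(rel))
  rel2 <- rel[perm, ]
  net2 <- build_network(spearman_all_pairs(rel2), rel2,
                        rho_min = 0.4, q_max = 0.1)
  key <- function(n) sort(paste(n$edges$taxon_a, n$edges$taxon_b))
  expect_identical(key(net), key(net2))
})
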