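# random symmetric zero-diagonal "distance-like" matrix
rand_dmat <- function(n, seed, ids = sprintf("s%02d", 1:n)) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- abs(rnorm(n * (n - 1) / 2))
  m <- m + t(m)
  dimnames(m) <- list(ids, ids)
  m
}

test_that("environment distances are plain Euclidean distances", {
  env <- data.frame(sample_id = c("a", "b", "c"), pH = c(1, 2, 4))
  d <- env_distance(env, "pH", standardize = FALSE)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 3)
  expect_equal(d["b", "c"], 2)
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))

  env$flat <- 5
  expect_true(attr(env_distance(env, "flat"), "degenerate"))

  env$x <- c(0, 1, 0)
  d2 <- env_distance(env, c("pH", "x"), standardize = FALSE)
  expect_equal(d2["a", "b"], sqrt(1 + 1), tolerance = 1e-12)
  expect_error(env_distance(env, "missing_var"), "missing variable")
})

test_that("MRM recovers an exact linear relation", {
  p1 <- rand_dmat(20, seed = 1)
  resp <- 2 * p1
  fit <- mrm(resp, list(x = p1), n_perm = 99, seed = 1)
  expect_equal(unname(fit$coef["x"]), 2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$coef_p[["x"]], 1 / 100)
})

test_that("orthogonal predictors split the variance share evenly", {
  n <- 30
  v1 <- rand_dmat(n, seed = 2)
  v2 <- rand_dmat(n, seed = 3)
  a <- v1[lower.tri(v1)]
  b <- v2[lower.tri(v2)]
  # orthogonalize b against a in the centered (regression) geometry
  b <- residuals(lm(b ~ a))
  a0 <- a - mean(a)
  b <- b * sqrt(sum(a0^2) / sum(b^2))        # equal centered norm
  m2 <- matrix(0, n, n)
  m2[lower.tri(m2)] <- b
  m2 <- m2 + t(m2)
  dimnames(m2) <- dimnames(v1)
  y <- matrix(0, n, n)
  y[lower.tri(y)] <- a + b
  y <- y + t(y)
  dimnames(y) <- dimnames(v1)
  fit <- mrm(y, list(p1 = v1, p2 = m2), n_perm = 9, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$share["p1"]), 0.5, tolerance = 0.05)
  expect_equal(unname(fit$share["p2"]), 0.5, tolerance = 0.05)
})

test_that("Mantel statistic equals 1 for identical and affine matrices", {
  d1 <- rand_dmat(15, seed = 4)
  mt <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$p, 1 / 100)
  aff <- 0.3 + 2 * d1
  diag(aff) <- 0  # keep a valid zero diagonal; off-diagonal affine
  mt2 <- mantel_test(d1, aff, method = "pearson", n_perm = 9, seed = 1)
  expect_gt(mt2$r, 0.99)
  flat <- d1 * 0
  expect_true(mantel_test(d1, flat, n_perm = 9, seed = 1)$flagged)
})

test_that("Mantel r agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  d1 <- rand_dmat(20, seed = 5)
  d2 <- rand_dmat(20, seed = 6)
  ours <- mantel_test(d1, d2, n_perm = 9, seed = 1)$r
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 9)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("single-predictor MRM R2 equals the squared Pearson Mantel r", {
  d1 <- rand_dmat(18, seed = 7)
  d2 <- rand_dmat(18, seed = 8)
  fit <- mrm(d1, list(x = d2), n_perm = 9, seed = 1)
  mt <- mantel_test(d1, d2, method = "pearson", n_perm = 9, seed = 1)
  expect_equal(fit$r2, mt$r^2, tolerance = 1e-9)
})

test_that("permutation p-values are floored and reorder-invariant", {
  d1 <- rand_dmat(12, seed = 9)
  d2 <- rand_dmat(12, seed = 10)
  mt <- mantel_test(d1, d1, n_perm = 19, seed = 2)
  expect_gte(mt$p, 1 / 20)

  set.seed(20)
  ord <- sample(12)
  f1 <- mrm(d1, list(x = d2), n_perm = 0, seed = 1)
  f2 <- mrm(d1[ord, ord], list(x = d2[ord, ord]), n_perm = 0, seed = 1)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
})

test_that("collinearity screening retains pH and enforces the rho2 cap", {
  set.seed(11)
  env <- data.frame(sample_id = sprintf("s%02d", 1:40),
                    pH = runif(40, 4.5, 9))
  env$dup <- env$pH + rnorm(40, 0, 0.01)   # collinear with pH
  env$free <- rnorm(40)
  keep <- screen_env(env, rho2_max = 0.6)
  expect_true("pH" %in% keep)
  expect_false("dup" %in% keep)
  expect_true("free" %in% keep)
  r2 <- cor(as.matrix(env[, keep]), method = "spearman")^2
  diag(r2) <- 0
  expect_true(all(r2 < 0.6))
})

test_that("feature drivers attribute an exact pH-driven feature to pH", {
  env <- generate_env(40, n_covariates = 4, cov_cor = 0.3, seed = 12)
  topo <- data.frame(sample_id = env$sample_id,
                     complexity = 3 * env$pH - 1,
                     flat = 1)
  expect_warning(
    tab <- feature_driver_table(topo, env, features = c("complexity", "flat"),
                                n_perm = 49, seed = 1),
    "constant")
  expect_equal(nrow(tab), 1)
  expect_gt(tab$pH, 0.5)
  expect_true(all(tab$pH > tab[, sprintf("env_%02d", 1:4)]))
  expect_gt(tab$total_r2, 0.95)
})

test_that("edge-count drivers flag degenerate series and find planted signal", {
  env <- generate_env(30, n_covariates = 1, cov_cor = 0.2, seed = 13)
  set.seed(14)
  topo <- data.frame(sample_id = env$sample_id,
                     BB_pos = round(10 * env$pH),   # monotone in pH
                     BB_neg = rpois(30, 5),
                     BF_pos = 0, BF_neg = 0, FF_pos = 0, FF_neg = 0)
  res <- edge_count_driver_analysis(topo, env, n_perm = 199, seed = 1)
  bf <- res[res$series == "BF_pos", ]
  expect_true(all(bf$flagged))
  hit <- res[res$series == "BB_pos" & res$variable == "pH", ]
  expect_lt(hit$p, 0.05)
  expect_gt(hit$r, 0.5)
})
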