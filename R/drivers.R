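#' Euclidean distance matrix over environmental variables
#'
#' Pairwise Euclidean distances between samples on one or more (optionally
#' z-scored) environmental variables. Standardization is on by default so
#' distances are scale-free across variables measured in different units.
#'
#' @param env data.frame with `sample_id` and numeric variables.
#' @param variables variable name(s) to use.
#' @param standardize z-score each variable first (default TRUE).
#' @return Object of class `dist_matrix`: symmetric matrix with sample ids
#'   as dimnames, zero diagonal; attribute `degenerate` flags an all-zero
#'   matrix (constant variables).
#' @export
env_distance <- function(env, variables, standardize = TRUE) {
  stop_if_not(all(variables %in% names(env)),
              paste0("missing variable(s): ",
                     paste(setdiff(variables, names(env)), collapse = ", ")))
  v <- as.matrix(env[, variables, drop = FALSE])
  stop_if_not(is.numeric(v), "variables must be numeric")
  stop_if_not(!anyNA(v), "missing values in env variables")
  if (standardize) {
    v <- apply(v, 2, function(col) {
      s <- sd(col)
      if (s > 0) (col - mean(col)) / s else col * 0
    })
    if (!is.matrix(v)) v <- matrix(v, ncol = length(variables))
  }
  d <- as.matrix(dist(v))
  dist_matrix(d, env$sample_id, "euclidean")
}

dist_matrix <- function(m, ids, metric) {
  dimnames(m) <- list(ids, ids)
  structure(m, metric = metric, degenerate = all(m == 0),
            class = c("dist_matrix", "matrix", "array"))
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the vectorized lower triangle of a response
#' distance matrix on those of predictor distance matrices. Significance is
#' assessed by permuting the response matrix's rows and columns jointly
#' `n_perm` times and recomputing; `p = (1 + #{|stat_perm| >= |stat_obs|}) /
#' (1 + n_perm)`, applied to each coefficient and to R-squared. The
#' per-predictor variance share is the squared semi-partial correlation,
#' `R2_full - R2_without_that_predictor`.
#'
#' @param response a `dist_matrix` (or plain symmetric matrix).
#' @param predictors named list of predictor distance matrices on the same
#'   samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Object of class `mrm`: list with `coef`, `coef_p`, `r2`,
#'   `r2_p`, `share` (named per predictor), `n_perm`, `seed`, `collinear`
#'   (flag: some predictor was dropped by `lm` for collinearity).
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = 1) {
  stop_if_not(length(predictors) >= 1, "need >= 1 predictor")
  if (is.null(names(predictors))) {
    names(predictors) <- sprintf("pred_%d", seq_along(predictors))
  }
  n <- nrow(response)
  for (p in predictors) {
    stop_if_not(nrow(p) == n, "predictor/response sample mismatch")
  }
  y <- lower_tri(as.matrix(response))
  xmat <- vapply(predictors, function(p) lower_tri(as.matrix(p)),
                 numeric(length(y)))
  fit <- lm(y ~ xmat)
  cf <- coef(fit)[-1]
  names(cf) <- names(predictors)
  collinear <- anyNA(cf)
  r2 <- summary(fit)$r.squared
  # semi-partial shares: drop in R2 when one predictor is removed
  share <- vapply(seq_along(predictors), function(j) {
    if (length(predictors) == 1) return(r2)
    r2_red <- summary(lm(y ~ xmat[, -j, drop = FALSE]))$r.squared
    max(r2 - r2_red, 0)
  }, numeric(1))
  names(share) <- names(predictors)
  perm <- with_seed(seed, {
    cnt_cf <- rep(0, length(cf))
    cnt_r2 <- 0
    rm <- as.matrix(response)
    for (b in seq_len(n_perm)) {
      ord <- sample.int(n)
      yp <- lower_tri(rm[ord, ord])
      fp <- lm(yp ~ xmat)
      cfp <- coef(fp)[-1]
      cnt_cf <- cnt_cf + (abs(cfp) >= abs(cf) - 1e-12)
      cnt_r2 <- cnt_r2 + (summary(fp)$r.squared >= r2 - 1e-12)
    }
    list(cf = cnt_cf, r2 = cnt_r2)
  })
  structure(list(coef = cf,
                 coef_p = setNames((1 + perm$cf) / (1 + n_perm), names(cf)),
                 r2 = r2,
                 r2_p = (1 + perm$r2) / (1 + n_perm),
                 share = share, n_perm = n_perm, seed = seed,
                 collinear = collinear),
            class = "mrm")
}

#' @export
print.mrm <- function(x, ...) {
  cat(sprintf("MRM: R2 = %.4f (p = %.4g, %d permutations)\n",
              x$r2, x$r2_p, x$n_perm))
  print(data.frame(coef = x$coef, p = x$coef_p, share = x$share))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Pearson or Spearman) between the lower triangles, with a
#' permutation p-value from jointly permuting one matrix's rows and columns:
#' `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param d1,d2 distance matrices on the same samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r`, `p`, `method`, `n_perm`, `seed`, `flagged`
#'   (TRUE when a matrix is constant and r is undefined).
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 9999, seed = 1) {
  method <- match.arg(method)
  stop_if_not(nrow(d1) == nrow(d2), "sample sets must match")
  v1 <- lower_tri(as.matrix(d1))
  v2 <- lower_tri(as.matrix(d2))
  if (sd(v1) == 0 || sd(v2) == 0) {
    return(list(r = NA_real_, p = NA_real_, method = method,
                n_perm = n_perm, seed = seed, flagged = TRUE))
  }
  r <- cor(v1, v2, method = method)
  n <- nrow(d1)
  m1 <- as.matrix(d1)
  cnt <- with_seed(seed, {
    k <- 0
    for (b in seq_len(n_perm)) {
      ord <- sample.int(n)
      rp <- cor(lower_tri(m1[ord, ord]), v2, method = method)
      if (abs(rp) >= abs(r) - 1e-12) k <- k + 1
    }
    k
  })
  list(r = r, p = (1 + cnt) / (1 + n_perm), method = method,
       n_perm = n_perm, seed = seed, flagged = FALSE)
}

#' Screen environmental variables for collinearity
#'
#' Retains a subset of variables whose pairwise Spearman rho-squared stays
#' below `rho2_max`, greedily dropping the variable involved in the most
#' offending pairs (ties broken by column order). `pH` is always retained
#' first.
#'
#' @param env data.frame with `sample_id` and numeric variables.
#' @param rho2_max maximum allowed pairwise Spearman rho-squared.
#' @return Character vector of retained variable names.
#' @export
screen_env <- function(env, rho2_max = 0.6) {
  vars <- setdiff(names(env), "sample_id")
  v <- as.matrix(env[, vars, drop = FALSE])
  r2 <- cor(v, method = "spearman")^2
  diag(r2) <- 0
  keep <- vars
  pri <- c("pH", setdiff(keep, "pH"))  # protect pH from being dropped
  repeat {
    sub <- r2[keep, keep, drop = FALSE]
    bad <- colSums(sub >= rho2_max)
    if (all(bad == 0)) break
    cand <- setdiff(keep[bad == max(bad)], "pH")
    if (length(cand) == 0) cand <- keep[bad == max(bad)]
    keep <- setdiff(keep, cand[which.max(match(cand, pri))])
  }
  keep
}

#' Driver attribution for per-sample topological features
#'
#' For each topological feature, an MRM of the feature's Euclidean distance
#' across samples on the per-variable environment distances: the
#' Table-1-shaped matrix of per-variable explained-variance shares plus the
#' overall R-squared. Constant features are skipped with a warning.
#'
#' @param topo data.frame from [per_sample_topology()] (needs `sample_id`).
#' @param env environment data.frame on the same samples.
#' @param features feature columns to analyse; defaults to the ten
#'   network-level features plus `complexity`.
#' @param variables env variables to use; defaults to all.
#' @param n_perm,seed forwarded to [mrm()].
#' @return data.frame: one row per feature with per-variable shares (as
#'   fractions), `total_r2`, and `r2_p`.
#' @export
feature_driver_table <- function(topo, env, features = NULL, variables = NULL,
                                 n_perm = 999, seed = 1) {
  stop_if_not(nrow(topo) == nrow(env), "one topology row per sample required")
  if (is.null(features)) {
    features <- intersect(c("n_nodes", "n_edges", "average_degree",
                            "average_path_length", "density", "modularity",
                            "clustering_coefficient", "degree_centralization",
                            "betweenness_centralization",
                            "eigenvector_centralization", "complexity"),
                          names(topo))
  }
  if (is.null(variables)) variables <- setdiff(names(env), "sample_id")
  pred <- lapply(variables, function(v) env_distance(env, v))
  names(pred) <- variables
  out <- list()
  for (f in features) {
    vals <- topo[[f]]
    if (anyNA(vals) || sd(vals) == 0) {
      warning("skipping constant or incomplete feature: ", f)
      next
    }
    resp <- dist_matrix(as.matrix(dist(scale(vals))), env$sample_id,
                        "euclidean")
    fit <- mrm(resp, pred, n_perm = n_perm,
               seed = derive_seed(seed, match(f, features)))
    row <- as.data.frame(as.list(fit$share), optional = TRUE)
    names(row) <- variables
    row$total_r2 <- fit$r2
    row$r2_p <- fit$r2_p
    row <- cbind(data.frame(feature = f, stringsAsFactors = FALSE), row)
    out[[f]] <- row
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mantel tests relating per-sample edge counts to environmental factors
#'
#' For each of the six kingdom-by-sign edge-count series (BB/BF/FF x
#' positive/negative) across per-sample subnetworks, a Mantel test of its
#' Euclidean distance matrix against each environmental variable's distance
#' matrix. All-zero (or otherwise constant) count series are flagged and
#' skipped.
#'
#' @param topo data.frame from [per_sample_topology()] (contains the six
#'   count columns).
#' @param env environment data.frame on the same samples.
#' @param variables env variables; defaults to all.
#' @param n_perm,seed forwarded to [mantel_test()].
#' @return data.frame with `series`, `variable`, `r`, `p`, `flagged`.
#' @export
edge_count_driver_analysis <- function(topo, env, variables = NULL,
                                       n_perm = 9999, seed = 1) {
  series <- c("BB_pos", "BB_neg", "BF_pos", "BF_neg", "FF_pos", "FF_neg")
  stop_if_not(all(series %in% names(topo)),
              "per-sample edge partition counts missing")
  if (is.null(variables)) variables <- setdiff(names(env), "sample_id")
  out <- list()
  k <- 0
  for (s in series) {
    vals <- topo[[s]]
    degen <- sd(vals) == 0
    ds <- if (!degen) {
      dist_matrix(as.matrix(dist(vals)), env$sample_id, "euclidean")
    } else NULL
    for (v in variables) {
      k <- k + 1
      if (degen) {
        out[[k]] <- data.frame(series = s, variable = v, r = NA_real_,
                               p = NA_real_, flagged = TRUE,
                               stringsAsFactors = FALSE)
      } else {
        mt <- mantel_test(ds, env_distance(env, v), n_perm = n_perm,
                          seed = derive_seed(seed, k))
        out[[k]] <- data.frame(series = s, variable = v, r = mt$r, p = mt$p,
                               flagged = mt$flagged, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
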