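#' Assign pH-preference ecological clusters
#'
#' Each taxon is labeled `"high_pH"` when its relative abundance has a
#' significant positive Spearman correlation with sample pH, `"low_pH"` when
#' significantly negative, and `"other"` otherwise. Membership uses the raw
#' (unadjusted) p-value at `alpha`; an FDR-adjusted variant is available by
#' flag. Constant abundance vectors are labeled `"other"`.
#'
#' @param x an `otu_table`; converted to relative abundances by default
#'   (`use_counts = TRUE` correlates the raw counts instead).
#' @param ph numeric pH per sample (same order as columns of `x`).
#' @param alpha significance level for membership.
#' @param fdr adjust p-values (BH) before thresholding (default FALSE).
#' @param use_counts correlate raw values rather than proportions.
#' @return data.frame with `taxon_id`, `rho`, `p`, `cluster`.
#' @export
assign_clusters <- function(x, ph, alpha = 0.05, fdr = FALSE,
                            use_counts = FALSE) {
  stop_if_not(inherits(x, "otu_table"), "x must be an otu_table")
  stop_if_not(length(ph) == ncol(x), "pH needed for every sample")
  m <- if (use_counts) unclass(x) else unclass(to_relative(x))
  res <- apply(m, 1, function(v) {
    s <- spearman_rho_p(v, ph)
    c(s$rho, s$p)
  })
  rho <- res[1, ]
  p <- res[2, ]
  p_eff <- if (fdr) bh_adjust(p) else p
  cluster <- ifelse(p_eff < alpha & rho > 0, "high_pH",
                    ifelse(p_eff < alpha & rho < 0, "low_pH", "other"))
  data.frame(taxon_id = rownames(x), rho = unname(rho), p = unname(p),
             cluster = unname(cluster), stringsAsFactors = FALSE)
}

#' Levins' habitat niche breadth
#'
#' `B_i = 1 / sum_j p_ij^2` where `p_ij` is the proportion of taxon i's
#' total abundance found in sample j. B ranges from 1 (found in a single
#' sample: a habitat specialist) to N, the number of samples (perfectly
#' even: a generalist), and is invariant to rescaling a taxon's abundances,
#' so counts and proportions give the same value.
#'
#' @param x an `otu_table`.
#' @return Named numeric vector of B per taxon; `NA` for taxa with zero
#'   total abundance (undefined).
#' @export
niche_breadth <- function(x) {
  stop_if_not(inherits(x, "otu_table"), "x must be an otu_table")
  m <- unclass(x)
  tot <- rowSums(m)
  b <- rep(NA_real_, nrow(m))
  ok <- tot > 0
  pij <- m[ok, , drop = FALSE] / tot[ok]
  b[ok] <- 1 / rowSums(pij^2)
  setNames(b, rownames(m))
}

#' Compare niche breadth between ecological clusters
#'
#' Two-sided two-sample t-test (Welch by default) of B between two groups,
#' typically the high- and low-pH clusters.
#'
#' @param b numeric niche-breadth values.
#' @param labels group label per value; exactly two non-NA groups are used.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return list with `statistic`, `p`, `means` (named group means),
#'   `flagged` (TRUE when a group has < 2 members, where the test is
#'   undefined).
#' @export
compare_niche_breadth <- function(b, labels, var_equal = FALSE) {
  keep <- !is.na(b) & !is.na(labels)
  b <- b[keep]
  labels <- labels[keep]
  groups <- unique(labels)
  stop_if_not(length(groups) == 2, "need exactly 2 groups")
  ga <- b[labels == groups[1]]
  gb <- b[labels == groups[2]]
  means <- setNames(c(mean(ga), mean(gb)), groups)
  if (length(ga) < 2 || length(gb) < 2) {
    return(list(statistic = NA_real_, p = NA_real_, means = means,
                flagged = TRUE))
  }
  if (sd(ga) == 0 && sd(gb) == 0) {
    # degenerate: both groups constant; the test statistic is 0/0 or +/-Inf
    same <- means[1] == means[2]
    return(list(statistic = if (same) 0 else sign(means[1] - means[2]) * Inf,
                p = if (same) 1 else 0, means = means, flagged = TRUE))
  }
  tt <- t.test(ga, gb, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p = tt$p.value, means = means,
       flagged = FALSE)
}
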