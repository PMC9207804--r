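#' Select the core taxa entering network analysis
#'
#' Core taxa are those in the top fraction of taxa ranked by mean relative
#' abundance across samples AND detected (nonzero) in strictly more than
#' `min_prev` of samples. The abundance rank is taken per kingdom by default,
#' so bacteria and fungi each contribute their own most abundant taxa; a
#' joint ranking is available with `per_kingdom = FALSE`. Ties in mean
#' abundance are broken by taxon id so the cut is deterministic.
#'
#' @param x an `otu_table`; counts are converted to relative abundances.
#' @param top_frac fraction of taxa kept by abundance rank (0 < top_frac <= 1);
#'   the top `ceiling(top_frac * n)` taxa are eligible.
#' @param min_prev prevalence threshold; retention requires prevalence
#'   strictly greater than this.
#' @param per_kingdom rank within each kingdom separately (default TRUE).
#' @return An object of class `core_taxa`: list with `report` (data.frame:
#'   `taxon_id`, `kingdom`, `mean_rel_abund`, `prevalence`, `in_top`,
#'   `retained`) and `taxon_ids` (retained ids, in input order).
#' @export
select_core <- function(x, top_frac = 0.2, min_prev = 0.6,
                        per_kingdom = TRUE) {
  stop_if_not(inherits(x, "otu_table"), "x must be an otu_table")
  stop_if_not(nrow(x) > 0 && ncol(x) > 0, "empty table")
  stop_if_not(top_frac > 0 && top_frac <= 1, "top_frac must be in (0, 1]")
  stop_if_not(min_prev >= 0 && min_prev <= 1, "min_prev must be in [0, 1]")
  rel <- to_relative(x)
  mean_ab <- rowMeans(rel)
  prev <- rowMeans(unclass(x) > 0)
  kingdom <- otu_kingdom(x)
  in_top <- logical(nrow(x))
  names(in_top) <- rownames(x)
  groups <- if (per_kingdom) split(rownames(x), kingdom) else
    list(all = rownames(x))
  for (ids in groups) {
    k <- ceiling(top_frac * length(ids))
    ord <- ids[order(-mean_ab[ids], ids)]
    in_top[ord[seq_len(k)]] <- TRUE
  }
  retained <- in_top & prev > min_prev
  report <- data.frame(taxon_id = rownames(x),
                       kingdom = unname(kingdom),
                       mean_rel_abund = unname(mean_ab),
                       prevalence = unname(prev),
                       in_top = unname(in_top),
                       retained = unname(retained),
                       stringsAsFactors = FALSE)
  structure(list(report = report,
                 taxon_ids = rownames(x)[retained],
                 top_frac = top_frac, min_prev = min_prev,
                 per_kingdom = per_kingdom),
            class = "core_taxa")
}

#' @export
print.core_taxa <- function(x, ...) {
  kt <- table(x$report$kingdom[x$report$retained])
  cat(sprintf("Core taxa: %d of %d retained (top %.0f%% by mean abundance, prevalence > %.0f%%)\n",
              length(x$taxon_ids), nrow(x$report),
              100 * x$top_frac, 100 * x$min_prev))
  if (length(kt)) {
    cat("  ", paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), "\n")
  }
  invisible(x)
}
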