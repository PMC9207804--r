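#' Construct an OTU table
#'
#' The canonical abundance container used throughout the package: a numeric
#' taxa-by-samples matrix together with a kingdom label per taxon and a mode
#' flag saying whether entries are raw counts or relative abundances
#' (per-sample proportions summing to 1).
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; rownames
#'   are taxon ids, colnames sample ids. No negative entries.
#' @param kingdom character vector, one of `"bacteria"`/`"fungi"` per taxon;
#'   recycled if length 1.
#' @param mode `"counts"` or `"relative"`.
#' @return An object of class `otu_table`: the matrix with attributes
#'   `kingdom` (named character) and `mode`.
#' @export
otu_table <- function(counts, kingdom = "bacteria",
                      mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  stop_if_not(is.numeric(counts), "OTU table body must be numeric")
  stop_if_not(!anyNA(counts), "OTU table contains missing values")
  stop_if_not(all(counts >= 0), "OTU table contains negative values")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("taxon%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%03d", seq_len(ncol(counts)))
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  stop_if_not(length(dup) == 0,
              paste0("duplicated taxon id(s): ", paste(unique(dup), collapse = ", ")))
  if (length(kingdom) == 1) kingdom <- rep(kingdom, nrow(counts))
  stop_if_not(length(kingdom) == nrow(counts),
              "kingdom must have one entry per taxon")
  stop_if_not(all(kingdom %in% c("bacteria", "fungi")),
              "kingdom entries must be 'bacteria' or 'fungi'")
  if (mode == "relative") {
    cs <- colSums(counts)
    stop_if_not(all(abs(cs - 1) <= 1e-9),
                "relative-mode columns must each sum to 1")
  }
  structure(counts,
            kingdom = setNames(as.character(kingdom), rownames(counts)),
            mode = mode,
            class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples (%s)\n",
              nrow(x), ncol(x), otu_mode(x)))
  kt <- table(otu_kingdom(x))
  cat("  kingdoms:", paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), "\n")
  invisible(x)
}

#' Kingdom labels of an OTU table
#' @param x an `otu_table`.
#' @return Named character vector of kingdom per taxon.
#' @export
otu_kingdom <- function(x) attr(x, "kingdom")

#' Mode flag of an OTU table
#' @param x an `otu_table`.
#' @return `"counts"` or `"relative"`.
#' @export
otu_mode <- function(x) attr(x, "mode")

# Subset an OTU table keeping its attributes.
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  attr(m, "kingdom") <- NULL
  attr(m, "mode") <- NULL
  out <- m[i, j, drop = FALSE]
  structure(out,
            kingdom = attr(x, "kingdom")[rownames(out)],
            mode = attr(x, "mode"),
            class = class(x))
}

#' Convert a count table to relative abundances
#'
#' Closes each sample column to proportions (total-sum scaling), the form in
#' which abundance ranking, correlation, and niche breadth are computed.
#'
#' @param x an `otu_table` in counts mode.
#' @return An `otu_table` in relative mode; every column sums to 1.
#' @export
to_relative <- function(x) {
  stop_if_not(inherits(x, "otu_table"), "x must be an otu_table")
  if (otu_mode(x) == "relative") return(x)
  cs <- colSums(x)
  bad <- colnames(x)[cs <= 0]
  stop_if_not(length(bad) == 0,
              paste0("all-zero sample column(s): ", paste(bad, collapse = ", ")))
  otu_table(sweep(unclass(x), 2, cs, "/"), kingdom = otu_kingdom(x),
            mode = "relative")
}

#' Read an OTU table from a tab-separated file
#'
#' Expects a header row of sample ids and a leading taxon-id column
#' (taxa-by-samples orientation, the QIIME-era convention) or the transpose;
#' `'#'` comment lines are tolerated. Mode is inferred: an all-integer body
#' is treated as counts, otherwise as relative abundances.
#'
#' @param path file path.
#' @param orientation `"taxa_by_samples"` (default) or `"samples_by_taxa"`.
#' @param kingdom_path optional path to a two-column tab-separated file
#'   (taxon id, kingdom); taxa absent from it default to `"bacteria"`.
#' @return An `otu_table` in canonical taxa-by-samples orientation.
#' @export
read_otu_table <- function(path,
                           orientation = c("taxa_by_samples", "samples_by_taxa"),
                           kingdom_path = NULL) {
  orientation <- match.arg(orientation)
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 2, "table must have an id column and >=1 value column")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  stop_if_not(length(dup) == 0,
              paste0("duplicated id(s): ", paste(dup, collapse = ", ")))
  body <- as.matrix(df[, -1, drop = FALSE])
  stop_if_not(is.numeric(body), "table body must be numeric")
  stop_if_not(all(body >= 0), "negative values in table body")
  rownames(body) <- ids
  if (orientation == "samples_by_taxa") body <- t(body)
  mode <- if (all(body == round(body))) "counts" else "relative"
  kingdom <- rep("bacteria", nrow(body))
  names(kingdom) <- rownames(body)
  if (!is.null(kingdom_path)) {
    km <- read.delim(kingdom_path, header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
    hit <- intersect(km[[1]], rownames(body))
    kingdom[hit] <- km[[2]][match(hit, km[[1]])]
  }
  if (mode == "relative") {
    # re-close to guard against rounding in the file
    body <- sweep(body, 2, colSums(body), "/")
  }
  otu_table(body, kingdom = kingdom, mode = mode)
}

#' Write an OTU table (and kingdom map) to tab-separated files
#'
#' @param x an `otu_table`.
#' @param path output path for the taxa-by-samples table.
#' @param kingdom_path optional path for the taxon-to-kingdom map.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, kingdom_path = NULL) {
  df <- data.frame(taxon_id = rownames(x), unclass(x), check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(kingdom_path)) {
    write_tsv(data.frame(taxon_id = rownames(x), kingdom = otu_kingdom(x)),
              kingdom_path)
  }
  invisible(path)
}

#' Read an environmental-factor table
#'
#' Samples-by-variables tab-separated file with a leading sample-id column;
#' a `pH` column is required. Missing values are an error.
#'
#' @param path file path.
#' @return data.frame with a `sample_id` column and numeric variables.
#' @export
read_env_table <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  stop_if_not("pH" %in% names(df), "env table must contain a 'pH' column")
  stop_if_not(all(complete.cases(df)), "env table contains missing values")
  df
}

#' Write an environmental-factor table
#' @param env data.frame with `sample_id` first.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  write_tsv(env, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
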