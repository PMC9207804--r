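#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist ks.test lm p.adjust pt qnorm rgamma rmultinom
#'   rnorm runif sd t.test var wilcox.test complete.cases setNames coef
#'   fisher.test
#' @importFrom utils read.delim write.csv head
#' @importFrom graphics lines arrows
NULL

# Derive a reproducible substream seed (< 2^31) from a top-level seed and a
# stage offset, so each pipeline stage consumes an independent stream.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed %% 1000003L) * 10007 + as.double(offset) * 97) %%
    2147483647
  as.integer(s) + 1L
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# log(mean(exp(x))) without overflow.
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# Lower-triangle vector of a square symmetric matrix (column-major, j < i).
lower_tri <- function(m) m[lower.tri(m)]

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
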