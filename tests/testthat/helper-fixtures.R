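# Small simulated study reused across test files (kept small for speed).
small_sim <- function(seed = 11, n_samples = 40, n_bacteria = 120,
                      n_fungi = 30, n_guilds = 4, ...) {
  simulate_community(n_samples = n_samples, n_bacteria = n_bacteria,
                     n_fungi = n_fungi, n_guilds = n_guilds,
                     n_covariates = 5, seed = seed, ...)
}

# Tiny deterministic OTU table for exact checks.
tiny_otu <- function() {
  m <- matrix(c(2, 2, 0, 4,
                1, 0, 3, 0,
                5, 5, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("B001", "B002", "F001"),
                              paste0("s", 1:4)))
  otu_table(m, kingdom = c("bacteria", "bacteria", "fungi"))
}
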