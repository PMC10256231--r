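# Shared small fixtures, built in code.

# a fully populated grid whose analysis set is the (n_rows-2) x (n_cols-2)
# interior
full_design <- function(n_rows = 10, n_cols = 10, spacing = 0.5) {
  make_field_design(n_rows, n_cols, spacing, missing_fraction = 0, seed = 1)
}

# a small complete synthetic trial, cached per test file
small_trial <- local({
  cache <- NULL
  function(n_genes = 60, n_causal = 6, seed = 42) {
    key <- paste(n_genes, n_causal, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    val <- simulate_field_trial(sim_config(n_genes = n_genes,
                                           n_causal_genes = n_causal,
                                           seed = seed))
    cache <<- list(key = key, value = val)
    val
  }
})

# brute-force Moran's I: explicit double sum over ordered pairs
moran_brute <- function(x, C) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + C[i, j] * z[i] * z[j]
  (n / sum(C)) * num / sum(z^2)
}
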