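# shared fixtures: catalogue with proxies resolved, and a lean simulation
# config (no background panel, single population) for fast replicates
the_catalog <- function() {
  suppressWarnings(resolve_proxies(load_catalog()))
}

lean_config <- function(n_duos, seed = 1L, ...) {
  sim_config(seed = seed, n_duos = n_duos,
             structure = list(n_subpops = 1L, maf_divergence = 0,
                              n_background_snps = 0L),
             ...)
}

# a minimal complete dosage matrix over given rsids
toy_genotypes <- function(counts, rsids, ids = NULL) {
  mat <- matrix(as.integer(counts), ncol = length(rsids), byrow = TRUE)
  colnames(mat) <- rsids
  rownames(mat) <- ids %||% paste0("I", seq_len(nrow(mat)))
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
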