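# Small synthetic configurations shared across tests.

tiny_config <- function(...) {
  defaults <- list(n_genes = 200L, cell_types = c("NK", "T", "B"),
                   n_replicates = 4L, n_markers = 10L, n_leaky = 2L,
                   n_stromal = 2L, marker_fold = 8, dispersion = 0.1,
                   n_cells_per_type = 30L, seed = 42L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# deterministic log-CPM toy matrix with named dimensions
toy_matrix <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 5, 2), n_genes, n_samples,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
    m
  })
}
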