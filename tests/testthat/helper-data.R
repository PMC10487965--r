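# Shared in-code fixtures.

# small named normalized matrix with reproducible values
toy_norm <- function(n_genes = 10, n_cells = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_cells)), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}

# minimal valid count_matrix
toy_counts <- function(n_genes = 6, n_cells = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 4) + 1, n_genes, n_cells,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("c%d", seq_len(n_cells))))
  meta <- data.frame(barcode = colnames(m),
                     sample_id = rep(c("Ctrl_1", "Ctrl_2", "DKD_1", "DKD_2"),
                                     length.out = n_cells),
                     group = rep(c("Ctrl", "Ctrl", "DKD", "DKD"),
                                 length.out = n_cells),
                     cell_type = "TypeA", stringsAsFactors = FALSE)
  count_matrix(m, meta)
}

# a cached default simulation shared by several test files
sim_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 42))
    cache
  }
})
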