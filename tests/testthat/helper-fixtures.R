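# In-code fixtures shared across test files.

random_dataset <- function(n_genes = 6, cells_per_stage = c(10, 12),
                           seed = 1) {
  set.seed(seed)
  n_cells <- sum(cells_per_stage)
  vals <- matrix(rexp(n_genes * n_cells, rate = 0.5), n_genes, n_cells)
  dimnames(vals) <- list(paste0("g", seq_len(n_genes)),
                         paste0("c", seq_len(n_cells)))
  stages <- rep(paste0("t", seq_along(cells_per_stage)), cells_per_stage)
  ccne_dataset(vals, stages)
}

# plain-matrix variant of the same draw (for IO round trips)
random_matrix <- function(n_genes = 3, n_cells = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rexp(n_genes * n_cells), 4), n_genes, n_cells)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("c", seq_len(n_cells)))
  m
}

sweep_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      circ <- build_default_circuit()
      set.seed(42)
      ds <- generate_sweep(circ, sim_config(n_cells_per_s = 30))
      cache <<- list(dataset = ds,
                     fit = ccne(ds, complete_network(rownames(ds$values))))
    }
    cache
  }
})
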