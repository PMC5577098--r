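# Shared fixtures, all built in code.

# Perfectly separable two-class dataset: class means far apart relative to
# noise, so any sensible classifier is exact.
make_separable_dataset <- function(n_genes = 10, n_per_class = 12, seed = 42) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    genes <- paste0("g", seq_len(n_genes))
    samples <- paste0("s", seq_len(n))
    labels <- setNames(rep(c("pos", "neg"), each = n_per_class), samples)
    shift <- ifelse(labels == "pos", 5, -5)
    values <- matrix(rnorm(n_genes * n, sd = 0.1), n_genes, n,
                     dimnames = list(genes, samples))
    values <- sweep(values, 2L, shift, `+`)
    expression_dataset(values, labels, positive_label = "pos")
  })
}

# Pure-noise dataset: labels carry no information.
make_null_dataset <- function(n_genes = 50, n_per_class = 20, seed = 7) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    genes <- paste0("g", seq_len(n_genes))
    samples <- paste0("s", seq_len(n))
    values <- matrix(rnorm(n_genes * n), n_genes, n,
                     dimnames = list(genes, samples))
    labels <- setNames(rep(c("pos", "neg"), each = n_per_class), samples)
    expression_dataset(values, labels, positive_label = "pos")
  })
}

# Small labeled simulation for pipeline-level tests.
make_small_sim <- function(seed = 1, delta = 2, n_pathways = 8,
                           n_informative = 2, n_per_class = 20,
                           n_genes = 200) {
  simulate_expression(simulation_config(
    n_genes = n_genes, n_pathways = n_pathways,
    pathway_size_range = c(5, 15),
    n_informative_pathways = n_informative,
    delta = delta, rho = 0.3, n_pos = n_per_class, n_neg = n_per_class,
    noise_sd = 1, seed = seed
  ))
}

# All 0/1 vectors of a given length, as rows of a matrix.
all_binary_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
}
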