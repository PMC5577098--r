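#' Configuration for the synthetic expression generator
#'
#' Defines the study conditions the simulator emulates: a two-class
#' expression matrix in which a subset of pathways carries a mean-shift class
#' signal against equicorrelated Gaussian noise. Defaults mirror a
#' chemotherapy-response cohort: a roughly 1:4 class imbalance
#' (50 positive vs 195 negative), pathway sizes in the tens of genes, and a
#' moderate per-gene effect.
#'
#' @param n_genes Total number of genes.
#' @param n_pathways Number of pathways in the generated GMT.
#' @param pathway_size_range Integer pair `(min, max)`; each pathway's size
#'   is drawn uniformly from this range. Pathways may overlap.
#' @param n_informative_pathways Number of pathways whose member genes carry
#'   the class signal.
#' @param delta Effect size: mean shift, in units of `noise_sd`, added to
#'   informative-pathway genes in positive-class samples.
#' @param rho Within-pathway gene-gene noise correlation in `[0, 1)`;
#'   implemented as an equicorrelated single-factor block per pathway.
#' @param n_pos,n_neg Samples per class.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param positive_label,negative_label Class label strings.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_pathways = 50,
                              pathway_size_range = c(10, 40),
                              n_informative_pathways = 5,
                              delta = 1, rho = 0.3,
                              n_pos = 50, n_neg = 195,
                              noise_sd = 1,
                              positive_label = "pCR",
                              negative_label = "RD",
                              seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_informative_pathways = as.integer(n_informative_pathways),
    delta = delta, rho = rho,
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    noise_sd = noise_sd,
    positive_label = positive_label, negative_label = negative_label,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_pathways < 1L) {
    abort("n_genes and n_pathways must be positive.")
  }
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1L] < 1L ||
      cfg$pathway_size_range[1L] > cfg$pathway_size_range[2L]) {
    abort("pathway_size_range must be an increasing pair of positive integers.")
  }
  if (cfg$pathway_size_range[2L] > cfg$n_genes) {
    abort("pathway_size_range must fit within n_genes.")
  }
  if (cfg$n_informative_pathways > cfg$n_pathways ||
      cfg$n_informative_pathways < 0L) {
    abort("n_informative_pathways must be between 0 and n_pathways.")
  }
  if (cfg$delta < 0) abort("delta must be >= 0.")
  if (cfg$rho < 0 || cfg$rho >= 1) abort("rho must be in [0, 1).")
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0.")
  if (cfg$n_pos < 2L || cfg$n_neg < 2L) abort("each class needs >= 2 samples.")
  if (identical(cfg$positive_label, cfg$negative_label)) {
    abort("class labels must differ.")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a two-class expression dataset with pathway-structured signal
#'
#' Background genes are i.i.d. `Normal(0, noise_sd^2)`. Within every pathway
#' the member genes share a latent factor with loading `sqrt(rho)`, giving an
#' equicorrelated noise block (pairwise correlation `rho`); a gene in several
#' pathways receives its factor from the first pathway that sampled it. Genes
#' of informative pathways additionally get `+delta * noise_sd` in
#' positive-class samples. Pathway membership is sampled without replacement
#' per pathway, so pathways may overlap.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (a labeled [expression_dataset()]),
#'   `gene_sets` (the matching `gene_set_collection`), and
#'   `informative_pathways` (character vector of ground-truth signal-carrying
#'   pathway IDs).
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_genes = 200, n_pathways = 10, n_pos = 20, n_neg = 20, seed = 7))
#' sim$dataset
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_genes <- config$n_genes
  n_pathways <- config$n_pathways
  n <- config$n_pos + config$n_neg
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n))
  labels <- setNames(
    c(rep(config$positive_label, config$n_pos),
      rep(config$negative_label, config$n_neg)),
    samples
  )

  with_seed(derive_seed(config$seed, STAGE[["simulate"]]), {
    sizes <- sample(seq(config$pathway_size_range[1L],
                        config$pathway_size_range[2L]),
                    n_pathways, replace = TRUE)
    membership <- lapply(sizes, function(k) sample(genes, k, replace = FALSE))
    names(membership) <- sprintf("pw%03d", seq_len(n_pathways))
    informative <- if (config$n_informative_pathways > 0L) {
      sample(names(membership), config$n_informative_pathways)
    } else {
      character(0)
    }

    # Idiosyncratic noise plus one latent factor per pathway; each gene's
    # factor comes from the first pathway that claimed it, so overlapping
    # pathways share correlated genes.
    rho <- config$rho
    eps <- matrix(rnorm(n_genes * n, sd = 1), n_genes, n,
                  dimnames = list(genes, samples))
    values <- sqrt(1 - rho) * eps
    assigned <- setNames(rep(FALSE, n_genes), genes)
    for (pw in names(membership)) {
      members <- membership[[pw]]
      fresh <- members[!assigned[members]]
      if (length(fresh) > 0L && rho > 0) {
        f <- rnorm(n)
        values[fresh, ] <- values[fresh, , drop = FALSE] +
          sqrt(rho) * matrix(f, length(fresh), n, byrow = TRUE)
      }
      assigned[members] <- TRUE
    }
    values[!assigned, ] <- eps[!assigned, , drop = FALSE] # pure i.i.d. background
    values <- values * config$noise_sd

    if (length(informative) > 0L && config$delta > 0) {
      sig_genes <- unique(unlist(membership[informative]))
      pos_idx <- which(labels == config$positive_label)
      values[sig_genes, pos_idx] <- values[sig_genes, pos_idx, drop = FALSE] +
        config$delta * config$noise_sd
    }

    list(
      dataset = expression_dataset(values, labels = labels,
                                   positive_label = config$positive_label),
      gene_sets = structure(
        membership,
        pathway_names = setNames(paste("simulated pathway", names(membership)),
                                 names(membership)),
        class = c("gene_set_collection", "list")
      ),
      informative_pathways = sort(informative)
    )
  })
}

#' Stratified train/test split
#'
#' Randomly partitions the samples into a training and a testing dataset,
#' preserving the class ratio on each side.
#'
#' @param dataset A labeled [expression_dataset()].
#' @param train_fraction Fraction of each class assigned to training, in
#'   `(0, 1)`.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both
#'   [expression_dataset()]s over disjoint sample sets whose union is the
#'   input.
#' @export
split_dataset <- function(dataset, train_fraction = 0.5, seed = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$labels)) abort("dataset must be labeled to split.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be strictly between 0 and 1.")
  }
  ids <- sample_ids(dataset)
  train_ids <- with_seed(derive_seed(seed, STAGE[["split"]]), {
    unlist(lapply(split(ids, dataset$labels[ids]), function(class_ids) {
      k <- round(length(class_ids) * train_fraction)
      sample(class_ids, k)
    }), use.names = FALSE)
  })
  test_ids <- setdiff(ids, train_ids)
  split_counts <- function(s) table(factor(dataset$labels[s],
                                           levels = unique(dataset$labels)))
  if (any(split_counts(train_ids) < 2L) || any(split_counts(test_ids) < 2L)) {
    abort("Each class must keep >= 2 samples on both sides of the split.")
  }
  list(
    train = subset_samples(dataset, ids[ids %in% train_ids]),
    test = subset_samples(dataset, ids[ids %in% test_ids])
  )
}
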