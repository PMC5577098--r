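#' Screen genes for differential expression between the two classes
#'
#' Per-gene two-sample test on the (full, unbalanced) training set. The
#' default is the moderated t-test with empirical-Bayes variance shrinkage
#' across genes (limma's `lmFit()`/`eBayes()` on a two-group design), which
#' is the standard screen for array-scale expression; a plain Welch t-test
#' is available via `method = "welch"`. A gene is flagged differentially
#' expressed when its raw p-value falls below `alpha`; no multiplicity
#' correction is applied by default (`adjust = "none"`), matching the
#' nominal-cutoff screening convention, with Benjamini-Hochberg available
#' via `adjust = "BH"`.
#'
#' Genes with zero variance in both classes get `p_value = 1` and are never
#' flagged.
#'
#' @param train A labeled [expression_dataset()] with >= 2 samples per class.
#' @param alpha Significance cutoff in `(0, 1)`; default 0.05.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param adjust P-value adjustment passed to [stats::p.adjust()];
#'   `"none"` (default) or any `p.adjust` method. The cutoff is applied to
#'   the adjusted values.
#' @return A tibble with one row per gene, columns `gene_id`, `statistic`,
#'   `p_value`, `is_de`, in the matrix's gene order.
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_genes = 100, n_pathways = 5, delta = 2, n_pos = 20, n_neg = 20,
#'   seed = 3))
#' de <- screen_de_genes(sim$dataset)
#' sum(de$is_de)
#' @export
screen_de_genes <- function(train, alpha = 0.05,
                            method = c("moderated", "welch"),
                            adjust = "none") {
  stopifnot(inherits(train, "expression_dataset"))
  method <- match.arg(method)
  if (is.null(train$labels)) abort("training dataset must be labeled.")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1).")
  labs <- train$labels
  if (any(table(labs) < 2L)) abort("each class needs >= 2 training samples.")
  grp <- factor(labs == train$positive_label, levels = c(FALSE, TRUE))
  x <- train$values

  if (method == "moderated") {
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(x, design))
    statistic <- fit$t[, 2L]
    p <- fit$p.value[, 2L]
  } else {
    pos <- x[, grp == TRUE, drop = FALSE]
    neg <- x[, grp == FALSE, drop = FALSE]
    res <- vapply(seq_len(nrow(x)), function(i) {
      if (var(pos[i, ]) == 0 && var(neg[i, ]) == 0) return(c(0, 1))
      tt <- stats::t.test(pos[i, ], neg[i, ])
      c(unname(tt$statistic), tt$p.value)
    }, numeric(2L))
    statistic <- res[1L, ]
    p <- res[2L, ]
  }
  # degenerate genes (zero variance everywhere) yield NaN under shrinkage
  p[!is.finite(p)] <- 1
  statistic[!is.finite(statistic)] <- 0
  p_adj <- stats::p.adjust(p, method = adjust)
  tibble::tibble(
    gene_id = gene_ids(train),
    statistic = unname(statistic),
    p_value = unname(p_adj),
    is_de = unname(p_adj < alpha)
  )
}

#' Intersect pathways with the differentially expressed gene list
#'
#' Maps each pathway to its differentially expressed member genes that are
#' present in the expression matrix ("DE pathways"); these intersections are
#' the feature sets of the base classifiers. Matching is exact,
#' case-sensitive string match; pathways whose intersection is empty are
#' dropped.
#'
#' @param gene_sets A `gene_set_collection` from [read_gmt()] or
#'   [simulate_expression()].
#' @param de A DE tibble from [screen_de_genes()].
#' @param universe Character vector of genes present in the expression
#'   matrix; defaults to `de$gene_id`.
#' @return A tibble with one row per surviving pathway, columns
#'   `pathway_id`, `feature_genes` (list column, ordered as in the pathway
#'   file), `n_features`, `n_pathway_genes`; input pathway order preserved.
#'   Errors when no pathway survives.
#' @export
map_pathways_to_de <- function(gene_sets, de, universe = de$gene_id) {
  de_genes <- de$gene_id[de$is_de]
  keep <- intersect(de_genes, universe)
  out <- tibble::tibble(
    pathway_id = names(gene_sets),
    feature_genes = lapply(gene_sets, function(g) g[g %in% keep]),
    n_features = unname(vapply(feature_genes, length, integer(1L))),
    n_pathway_genes = unname(lengths(gene_sets))
  )
  out <- dplyr::filter(out, .data$n_features > 0L)
  if (nrow(out) == 0L) {
    abort("No DE pathway: no pathway shares a gene with the DE list; the pipeline cannot proceed.")
  }
  out
}
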