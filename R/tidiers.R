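#' Tidy a fitted pathway ensemble
#'
#' One row per final ensemble member: pathway, number of feature genes (out
#' of the pathway's size in the gene-set file), cross-validation accuracy,
#' and overall diversity within the top-N pool.
#'
#' @param x A `pathway_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `pathway_id`, `n_features`,
#'   `n_pathway_genes`, `mean_cv_accuracy`, `overall_diversity`.
#' @export
tidy.pathway_ensemble <- function(x, ...) {
  rec <- x$records
  idx <- match(names(x$learners), rec$pathway_id)
  tibble::tibble(
    pathway_id = names(x$learners),
    n_features = rec$n_features[idx],
    n_pathway_genes = if ("n_pathway_genes" %in% names(rec)) {
      rec$n_pathway_genes[idx]
    } else {
      NA_integer_
    },
    mean_cv_accuracy = rec$mean_cv_accuracy[idx],
    overall_diversity = unname(x$overall_diversity[names(x$learners)])
  )
}

#' One-row summary of a fitted pathway ensemble
#'
#' @param x A `pathway_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: number of DE genes, number of DE pathways, the
#'   pool size, the best prefix size `m`, the final ensemble size, the best
#'   prefix cross-validation accuracy, and `theta`.
#' @export
glance.pathway_ensemble <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    n_de_genes = sum(x$de$is_de),
    n_de_pathways = nrow(x$records),
    pool_size = length(tr$S),
    m = tr$m,
    ensemble_size = length(tr$S_doubleprime),
    best_prefix_accuracy = max(tr$prefix_accuracies$accuracy),
    theta = tr$theta
  )
}

#' Tidy ensemble test metrics
#'
#' @param x An `ensemble_metrics` object from [evaluate_on_test()].
#' @param ... Unused.
#' @return The per-metric summary tibble (`metric`, `mean`, `sd`,
#'   `n_defined`).
#' @export
tidy.ensemble_metrics <- function(x, ...) x$summary

#' One-row metric means
#'
#' @param x An `ensemble_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with one column per metric mean.
#' @export
glance.ensemble_metrics <- function(x, ...) {
  tibble::as_tibble(setNames(as.list(x$summary$mean), x$summary$metric))
}

#' Plot the ensemble-size accuracy curve
#'
#' Cross-validated majority-vote accuracy of the growing prefix of the
#' diversity-ordered pool, with the selected size `m` marked — the
#' diagnostic view of the preliminary optimization.
#'
#' @param object A `pathway_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_ensemble <- function(object, ...) {
  df <- object$trace$prefix_accuracies
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$trace$m, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "number of base classifiers (prefix of S*)",
      y = "mean CV accuracy of majority vote",
      title = "Ensemble accuracy vs size",
      subtitle = sprintf("selected m = %d; final ensemble |S''| = %d",
                         object$trace$m,
                         length(object$trace$S_doubleprime))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-run test metrics
#'
#' @param object An `ensemble_metrics` object.
#' @param ... Unused.
#' @return A ggplot object (boxplot of per-run metric values).
#' @export
autoplot.ensemble_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$runs, -"run",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "per-run value",
                  title = "Test metrics over balanced subsample runs") +
    ggplot2::theme_minimal()
}

#' Plot the learner diversity matrix
#'
#' Heatmap of pairwise disagreement among the top-N pool, in overall
#' diversity order.
#'
#' @param model A `pathway_ensemble`.
#' @return A ggplot object.
#' @export
plot_diversity <- function(model) {
  stopifnot(inherits(model, "pathway_ensemble"))
  D <- model$diversity
  ord <- model$trace$S_star
  df <- tibble::as_tibble(as.data.frame(as.table(D[ord, ord, drop = FALSE])),
                          .name_repair = "minimal")
  names(df) <- c("learner_i", "learner_k", "diversity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$learner_i, y = .data$learner_k,
                                   fill = .data$diversity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "D",
                  title = "Pairwise disagreement diversity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
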