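#' Score every DE pathway's base learner
#'
#' Trains and cross-validates one pathway-restricted SVM per row of the DE
#' pathway table, under a single shared resampling stream: every run draws
#' one balanced subsample and one stratified fold partition used by all
#' learners, so accuracies and correctness vectors are directly comparable
#' across pathways (and the pairwise diversity of any two learners is
#' well-defined per run).
#'
#' @param dataset A labeled training [expression_dataset()].
#' @param de_pathways A DE pathway tibble from [map_pathways_to_de()] (or
#'   any tibble with `pathway_id` and list column `feature_genes`).
#' @param protocol A [cv_protocol()].
#' @param kernel SVM kernel, `"radial"` or `"linear"`.
#' @return A `learner_records` tibble, one row per pathway, columns
#'   `pathway_id`, `feature_genes`, `n_features`, `mean_cv_accuracy`,
#'   `sd_cv_accuracy`, `correctness` (list of named 0/1 vectors over the full
#'   sample set). The underlying out-of-fold prediction cache is attached as
#'   attribute `"cv_cache"` for downstream reuse.
#' @export
evaluate_learners <- function(dataset, de_pathways, protocol = cv_protocol(),
                              kernel = "radial") {
  if (nrow(de_pathways) == 0L) abort("empty DE pathway table.")
  feature_sets <- setNames(de_pathways$feature_genes, de_pathways$pathway_id)
  cache <- build_cv_cache(dataset, feature_sets, protocol, kernel = kernel)
  run_acc <- cache_run_accuracies(cache)
  summ <- run_acc |>
    dplyr::group_by(.data$learner_id) |>
    dplyr::summarise(
      mean_cv_accuracy = mean(.data$accuracy),
      sd_cv_accuracy = if (dplyr::n() > 1L) sd(.data$accuracy) else 0,
      .groups = "drop"
    )
  corr <- cache_correctness_vectors(cache)
  out <- tibble::tibble(
    pathway_id = de_pathways$pathway_id,
    feature_genes = de_pathways$feature_genes,
    n_features = vapply(de_pathways$feature_genes, length, integer(1L)),
    n_pathway_genes = if ("n_pathway_genes" %in% names(de_pathways)) {
      de_pathways$n_pathway_genes
    } else {
      NA_integer_
    },
    mean_cv_accuracy = summ$mean_cv_accuracy[match(de_pathways$pathway_id,
                                                   summ$learner_id)],
    sd_cv_accuracy = summ$sd_cv_accuracy[match(de_pathways$pathway_id,
                                               summ$learner_id)],
    correctness = lapply(de_pathways$pathway_id, function(id) corr[, id])
  )
  attr(out, "cv_cache") <- cache
  class(out) <- c("learner_records", class(out))
  out
}

#' Rank base learners by accuracy and keep the top N
#'
#' Sorts learners by mean cross-validation accuracy in descending order
#' (ties broken by pathway ID, ascending) and keeps the first
#' `min(top_n, available)`; this ordered set is the pool S from which the
#' ensemble is selected.
#'
#' @param records A `learner_records` tibble from [evaluate_learners()].
#' @param top_n Pool size; default 35.
#' @return The top rows of `records` in rank order, with a `rank` column
#'   prepended; the cv cache attribute is carried along. Warns when fewer
#'   than `top_n` learners are available.
#' @export
rank_learners <- function(records, top_n = 35) {
  if (nrow(records) == 0L) abort("no learner records to rank.")
  if (top_n < 1L) abort("top_n must be >= 1.")
  cache <- attr(records, "cv_cache")
  ord <- order(-records$mean_cv_accuracy, records$pathway_id)
  if (nrow(records) < top_n) {
    warn(sprintf("only %d learners available; keeping all (top_n = %d).",
                 nrow(records), as.integer(top_n)))
  }
  out <- records[ord, ][seq_len(min(top_n, nrow(records))), ]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1L)
  attr(out, "cv_cache") <- cache
  out
}
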