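#' Confusion counts for two-class predictions
#'
#' @param predicted,truth Aligned label vectors of equal positive length.
#' @param positive_label The class counted as positive.
#' @return A named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion(c("a", "a", "b"), c("a", "b", "b"), positive_label = "a")
#' @export
confusion <- function(predicted, truth, positive_label) {
  if (length(predicted) == 0L) abort("empty prediction vector.")
  if (length(predicted) != length(truth)) {
    abort(sprintf("alignment mismatch: %d predictions vs %d truths.",
                  length(predicted), length(truth)))
  }
  if (!is.null(names(predicted)) && !is.null(names(truth)) &&
      !identical(names(predicted), names(truth))) {
    abort("predicted and truth sample names differ.")
  }
  p <- predicted == positive_label
  t_ <- truth == positive_label
  c(
    TP = sum(p & t_), TN = sum(!p & !t_),
    FP = sum(p & !t_), FN = sum(!p & t_)
  )
}

#' Confusion-matrix performance metrics
#'
#' The five standard two-class metrics:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and
#' F-score `2*TP/(2*TP+FP+FN)`. A metric whose denominator is zero is
#' returned as `NA` (undefined) rather than coerced to 0, and is excluded
#' from across-run averages by [evaluate_on_test()].
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` (from
#'   [confusion()]).
#' @return A tibble with columns `metric` and `value` (five rows).
#' @examples
#' compute_metrics(c(TP = 3, TN = 2, FP = 1, FN = 1))
#' @export
compute_metrics <- function(counts) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts))) {
    abort("counts must contain TP, TN, FP, FN.")
  }
  if (any(counts[need] < 0) || sum(counts[need]) < 1) {
    abort("counts must be non-negative and sum to >= 1.")
  }
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    metric = c("accuracy", "precision", "sensitivity", "specificity",
               "f_score"),
    value = c(
      (tp + tn) / (tp + tn + fp + fn),
      safe_div(tp, tp + fp),
      safe_div(tp, tp + fn),
      safe_div(tn, tn + fp),
      safe_div(2 * tp, 2 * tp + fp + fn)
    )
  )
}

#' Score a fitted ensemble on held-out data by repeated balanced subsampling
#'
#' For each run, a class-balanced random subsample of the test set is drawn
#' (seeded from the protocol), the already-fitted model predicts it, and the
#' five confusion metrics are computed; means and standard deviations are
#' taken over runs. The model is never retrained on test data. Metrics
#' undefined in a run (zero denominator) are excluded from that metric's
#' mean and SD.
#'
#' @param model A fitted `pathway_ensemble`.
#' @param test A labeled [expression_dataset()], disjoint from the training
#'   samples (caller-asserted).
#' @param protocol A [cv_protocol()]; `n_runs` and `seed` control the
#'   subsampling (folds are not used since the model is fixed). With
#'   `balance = FALSE`, every run scores the full test set and the run
#'   dimension is degenerate.
#' @return An `ensemble_metrics` object with `runs` (tibble: `run` plus one
#'   column per metric) and `summary` (tibble: `metric`, `mean`, `sd`,
#'   `n_defined`). `tidy()` returns the summary, `glance()` a one-row
#'   tibble of means, `autoplot()` a per-run distribution plot.
#' @export
evaluate_on_test <- function(model, test, protocol = cv_protocol()) {
  stopifnot(inherits(model, "pathway_ensemble"),
            inherits(test, "expression_dataset"))
  if (is.null(test$labels)) abort("test dataset must be labeled.")
  tab <- table(test$labels)
  if (any(tab < 2L)) abort("each test class needs >= 2 samples.")
  pos <- model$positive_label

  runs <- lapply(seq_len(protocol$n_runs), function(r) {
    run_seed <- derive_seed(protocol$seed, STAGE[["test_eval"]], r)
    sub <- if (protocol$balance) {
      balanced_sample_ids(test$labels, run_seed)
    } else {
      sample_ids(test)
    }
    eval_set <- subset_samples(test, sub)
    pred <- predict(model, eval_set)
    m <- compute_metrics(confusion(pred, eval_set$labels, pos))
    tibble::tibble(run = r, !!!setNames(as.list(m$value), m$metric))
  })
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    tidyr::pivot_longer(-"run", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1L) sd(.data$value, na.rm = TRUE) else 0,
      n_defined = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, c("accuracy", "precision",
                                         "sensitivity", "specificity",
                                         "f_score")))
  structure(list(runs = runs, summary = summary, positive_label = pos),
            class = "ensemble_metrics")
}

#' @export
print.ensemble_metrics <- function(x, ...) {
  cat(sprintf("<ensemble_metrics> %d run(s), positive class: %s\n",
              nrow(x$runs), x$positive_label))
  print(x$summary)
  invisible(x)
}
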