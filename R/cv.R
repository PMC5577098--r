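#' Cross-validation protocol for learner and ensemble scoring
#'
#' Describes the repeated balanced cross-validation scheme used throughout:
#' each run draws a fresh class-balanced subsample of the data (all minority
#' samples plus an equal-size random draw from the majority class), splits
#' it into stratified folds, trains on all folds but one and scores the
#' held-out fold. Accuracies are averaged over runs. The default protocol is
#' 100 runs of 5-fold cross-validation on balanced subsamples.
#'
#' @param n_runs Number of balanced-resample runs (>= 1); default 100.
#' @param n_folds Folds per run (>= 2); default 5.
#' @param balance Draw a balanced subsample each run (default `TRUE`); with
#'   `FALSE` every run uses the full sample set and only the fold partition
#'   varies.
#' @param seed Integer seed for the balanced-resample/fold stream.
#' @return A `cv_protocol` list.
#' @export
cv_protocol <- function(n_runs = 100, n_folds = 5, balance = TRUE, seed = 1) {
  if (n_runs < 1L) abort("n_runs must be >= 1.")
  if (n_folds < 2L) abort("n_folds must be >= 2.")
  structure(
    list(n_runs = as.integer(n_runs), n_folds = as.integer(n_folds),
         balance = isTRUE(balance), seed = as.integer(seed)),
    class = "cv_protocol"
  )
}

#' Draw a class-balanced subsample
#'
#' Keeps every sample of the minority class and a uniform random draw of
#' equal size from the majority class (e.g. 50 vs 195 becomes 50 vs 50).
#' Already-balanced data is returned with all samples.
#'
#' @param dataset A labeled [expression_dataset()].
#' @param seed Integer seed.
#' @return An [expression_dataset()] over the subsampled columns.
#' @export
balanced_subsample <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  ids <- balanced_sample_ids(dataset$labels, derive_seed(seed, STAGE[["subsample"]]))
  subset_samples(dataset, ids)
}

# Sample IDs of a balanced subsample, in original column order. Candidates
# are sorted before the seeded draw so the chosen SET depends only on the
# sample IDs and the seed, never on column order.
balanced_sample_ids <- function(labels, seed) {
  tab <- table(labels)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  min_ids <- sort(names(labels)[labels == minority])
  maj_ids <- sort(names(labels)[labels == majority])
  picked <- if (length(maj_ids) > length(min_ids)) {
    with_seed(seed, sample(maj_ids, length(min_ids)))
  } else {
    maj_ids
  }
  names(labels)[names(labels) %in% c(min_ids, picked)]
}

# Stratified fold assignment; re-draws (fresh RNG stream continuation) until
# every fold contains both classes, erroring after max_attempts.
stratified_folds <- function(labels, n_folds, seed, max_attempts = 100L) {
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      fold <- integer(length(labels))
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        fold[idx] <- (sample(seq_along(idx)) %% n_folds) + 1L
      }
      ok <- all(vapply(seq_len(n_folds), function(f) {
        length(unique(labels[fold == f])) == 2L &&
          length(unique(labels[fold != f])) == 2L
      }, logical(1L)))
      if (ok) return(fold)
    }
    abort(sprintf(
      "Could not build %d stratified folds with both classes per fold after %d attempts.",
      n_folds, max_attempts
    ))
  })
}

#' Train a pathway-restricted SVM
#'
#' Soft-margin SVM with the libsvm defaults the baseline protocol implies:
#' RBF kernel, `cost = 1`, `gamma = 1/p` with `p` the feature count.
#' Features are standardized to zero mean / unit variance using training
#' statistics only (constant features are centred and left unscaled); the
#' same statistics are applied at prediction time.
#'
#' @param dataset A labeled [expression_dataset()] (the training samples).
#' @param feature_genes Character vector of gene IDs to use as features;
#'   must all be present in the matrix.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @return A `pathway_svm` object usable with [predict()].
#' @export
train_svm <- function(dataset, feature_genes, kernel = c("radial", "linear")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  kernel <- match.arg(kernel)
  if (is.null(dataset$labels)) abort("training data must be labeled.")
  if (length(unique(dataset$labels)) < 2L) {
    abort("single-class training data: both classes are required to fit an SVM.")
  }
  missing <- setdiff(feature_genes, gene_ids(dataset))
  if (length(missing) > 0L) {
    abort(sprintf("feature gene(s) absent from matrix: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  x <- t(dataset$values[feature_genes, , drop = FALSE])
  fit_svm_raw(x, factor(dataset$labels), kernel)
}

# x: samples x features numeric matrix; y: factor with 2 levels.
fit_svm_raw <- function(x, y, kernel = "radial") {
  center <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = center, scale = scl)
  model <- e1071::svm(
    x = xs, y = y, kernel = kernel, cost = 1,
    gamma = 1 / ncol(x), scale = FALSE
  )
  structure(
    list(model = model, center = center, scale = scl,
         feature_genes = colnames(x), kernel = kernel),
    class = "pathway_svm"
  )
}

#' @export
predict.pathway_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_dataset")) {
    missing <- setdiff(object$feature_genes, gene_ids(newdata))
    if (length(missing) > 0L) {
      abort(sprintf("test matrix lacks feature gene(s): %s",
                    paste(head(missing, 5L), collapse = ", ")))
    }
    newdata <- t(newdata$values[object$feature_genes, , drop = FALSE])
  }
  xs <- scale(newdata[, object$feature_genes, drop = FALSE],
              center = object$center, scale = object$scale)
  as.character(predict(object$model, xs))
}

# ---- shared out-of-fold prediction cache -----------------------------------
#
# One pass over (run, fold, learner): every run draws ONE balanced subsample
# and ONE stratified fold partition shared by all learners, so learner
# accuracies, per-run correctness vectors (hence the averaged diversity
# matrix) and any ensemble's vote-based accuracy can all be read from the
# same out-of-fold predictions under identical seed streams.
build_cv_cache <- function(dataset, feature_sets, protocol, kernel = "radial") {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(protocol, "cv_protocol"))
  labs <- dataset$labels
  runs <- vector("list", protocol$n_runs)
  for (r in seq_len(protocol$n_runs)) {
    run_seed <- derive_seed(protocol$seed, STAGE[["cv_run"]], r)
    sub_ids <- if (protocol$balance) {
      balanced_sample_ids(labs, run_seed)
    } else {
      names(labs)
    }
    sub_labs <- labs[sub_ids]
    fold <- stratified_folds(sub_labs, protocol$n_folds,
                             derive_seed(run_seed, STAGE[["cv_run"]], 1L))
    xsub <- dataset$values[, sub_ids, drop = FALSE]
    pred <- matrix(NA_character_, length(sub_ids), length(feature_sets),
                   dimnames = list(sub_ids, names(feature_sets)))
    for (f in seq_len(protocol$n_folds)) {
      tr <- fold != f
      te <- !tr
      ytr <- factor(sub_labs[tr])
      for (k in seq_along(feature_sets)) {
        genes <- feature_sets[[k]]
        xtr <- t(xsub[genes, tr, drop = FALSE])
        fit <- fit_svm_raw(xtr, ytr, kernel)
        pred[te, k] <- predict(fit, t(xsub[genes, te, drop = FALSE]))
      }
    }
    runs[[r]] <- list(sub_ids = sub_ids, truth = unname(sub_labs), pred = pred)
  }
  structure(
    list(runs = runs, learner_ids = names(feature_sets),
         sample_ids = sample_ids(dataset),
         positive_label = dataset$positive_label, protocol = protocol),
    class = "cv_cache"
  )
}

# Per-run pooled out-of-fold accuracy, one row per (run, learner).
cache_run_accuracies <- function(cache) {
  do.call(rbind, lapply(seq_along(cache$runs), function(r) {
    run <- cache$runs[[r]]
    acc <- colMeans(run$pred == run$truth)
    data.frame(run = r, learner_id = names(acc), accuracy = unname(acc))
  }))
}

# Correctness over the full sample set: entry = 1 when the sample was
# classified correctly in a strict majority of the runs that held it out;
# samples never held out get 0.
cache_correctness_vectors <- function(cache) {
  ids <- cache$sample_ids
  K <- length(cache$learner_ids)
  correct <- matrix(0, length(ids), K, dimnames = list(ids, cache$learner_ids))
  seen <- matrix(0, length(ids), K, dimnames = list(ids, cache$learner_ids))
  for (run in cache$runs) {
    hit <- (run$pred == run$truth) * 1
    correct[run$sub_ids, ] <- correct[run$sub_ids, , drop = FALSE] + hit
    seen[run$sub_ids, ] <- seen[run$sub_ids, , drop = FALSE] + 1
  }
  out <- (correct > seen / 2) * 1L
  storage.mode(out) <- "integer"
  out
}

# Majority-vote accuracy of a member subset, per run, from cached
# predictions. tie_break: member column name whose vote decides even-split
# ties (the highest-accuracy member of the subset).
cache_ensemble_accuracy <- function(cache, members, positive_label, tie_break) {
  vapply(cache$runs, function(run) {
    votes <- ensemble_votes(run$pred[, members, drop = FALSE],
                            positive_label, tie_break)
    mean(votes == (run$truth == positive_label))
  }, numeric(1L))
}

# Logical vote per row: TRUE = positive class. pred: samples x members.
ensemble_votes <- function(pred, positive_label, tie_break) {
  T_ <- ncol(pred)
  pos <- rowSums(pred == positive_label)
  out <- pos * 2L > T_
  tie <- pos * 2L == T_
  if (any(tie)) {
    out[tie] <- pred[tie, tie_break] == positive_label
  }
  out
}

#' Score one feature set by repeated balanced cross-validation
#'
#' For each run, a balanced subsample is drawn, split into stratified folds,
#' and the SVM is trained on all folds but one and scored on the held-out
#' fold; the run accuracy pools the held-out predictions, and the reported
#' accuracy is the mean over runs. Also returns the per-sample correctness
#' vector over the full dataset: 1 when the sample was classified correctly
#' in a strict majority of the runs that held it out, else 0.
#'
#' @param dataset A labeled [expression_dataset()].
#' @param feature_genes Character vector of feature gene IDs.
#' @param protocol A [cv_protocol()].
#' @param kernel SVM kernel, `"radial"` or `"linear"`.
#' @return A list with `mean_cv_accuracy`, `sd_cv_accuracy`,
#'   `run_accuracies` (numeric vector, one per run), and `correctness`
#'   (named integer 0/1 vector over all samples).
#' @export
evaluate_learner_cv <- function(dataset, feature_genes, protocol = cv_protocol(),
                                kernel = "radial") {
  cache <- build_cv_cache(dataset, list(learner = feature_genes), protocol,
                          kernel = kernel)
  acc <- cache_run_accuracies(cache)$accuracy
  corr <- cache_correctness_vectors(cache)[, 1L]
  list(
    mean_cv_accuracy = mean(acc),
    sd_cv_accuracy = if (length(acc) > 1L) sd(acc) else 0,
    run_accuracies = acc,
    correctness = corr
  )
}
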