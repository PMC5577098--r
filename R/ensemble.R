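#' Reorder an accuracy-ranked learner pool by overall diversity
#'
#' Produces the diversity order S* from the accuracy order S: a stable sort
#' by overall diversity, descending, with ties kept in their original
#' (accuracy-rank) positions.
#'
#' @param S Character vector of learner (pathway) IDs in accuracy order.
#' @param od Named numeric vector of overall diversities covering `S`.
#' @return `S` reordered by decreasing `od`.
#' @export
reorder_by_od <- function(S, od) {
  if (!all(S %in% names(od))) abort("od must cover every learner in S.")
  S[order(-od[S], seq_along(S))]
}

#' Majority vote over base-classifier predictions
#'
#' The label receiving strictly more than half of the `T` votes wins;
#' equivalently the ensemble is correct exactly when at least
#' `floor(T/2 + 1)` members vote for the true class. For even `T` with an
#' exact split, the vote of the designated tie-breaking member (by
#' convention the ensemble member with the highest cross-validation
#' accuracy) decides.
#'
#' @param votes Character vector of per-member predicted labels for one
#'   sample (length `T >= 1`).
#' @param tie_break Index (or name) of the tie-breaking member within
#'   `votes`; default 1.
#' @return The winning label.
#' @examples
#' majority_vote(c("pos", "pos", "neg")) # "pos"
#' @export
majority_vote <- function(votes, tie_break = 1L) {
  if (length(votes) == 0L) abort("majority vote needs at least one vote.")
  tab <- table(votes)
  top <- tab[tab == max(tab)]
  if (length(top) == 1L) return(names(top))
  unname(votes[tie_break])
}

# Index (within `members`) of the tie-breaking learner: highest
# mean_cv_accuracy, ties by pathway_id ascending.
tie_break_member <- function(members, accuracies) {
  members[order(-accuracies[members], members)][1L]
}

#' Cross-validated accuracy of a majority-vote ensemble
#'
#' Scores a set of base learners combined by majority vote under the same
#' repeated balanced cross-validation scheme as single-learner scoring: in
#' each run's fold split, every member is retrained on its own feature genes
#' and the held-out prediction is the members' majority vote.
#'
#' @param dataset A labeled [expression_dataset()].
#' @param feature_sets Named list (pathway ID -> feature gene vector) of the
#'   member learners.
#' @param protocol A [cv_protocol()].
#' @param kernel SVM kernel.
#' @return A list with `mean_accuracy` and `run_accuracies`.
#' @export
evaluate_ensemble_cv <- function(dataset, feature_sets,
                                 protocol = cv_protocol(),
                                 kernel = "radial") {
  if (length(feature_sets) == 0L) abort("ensemble must have >= 1 member.")
  cache <- build_cv_cache(dataset, feature_sets, protocol, kernel = kernel)
  run_acc <- cache_run_accuracies(cache)
  mean_acc <- tapply(run_acc$accuracy, run_acc$learner_id, mean)
  tb <- tie_break_member(names(feature_sets), mean_acc)
  acc <- cache_ensemble_accuracy(cache, names(feature_sets),
                                 cache$positive_label, tb)
  list(mean_accuracy = mean(acc), run_accuracies = acc)
}

#' Incremental prefix search over the diversity-ordered pool
#'
#' The preliminary optimization: members of S* are added to the ensemble
#' one at a time and each prefix is scored by the shared cross-validated
#' majority vote; `m` is the smallest prefix size achieving the maximum
#' mean accuracy, and `S' = S*[1:m]`.
#'
#' @param records A `learner_records` tibble from [evaluate_learners()]
#'   (carrying the out-of-fold prediction cache).
#' @param S_star Character vector: the pool in overall-diversity order.
#' @param min_prefix Smallest prefix size to evaluate; default 1.
#' @return A list with `m` (integer), `prefix_accuracies` (tibble with
#'   columns `size`, `accuracy`), and `S_prime`.
#' @export
preliminary_optimize <- function(records, S_star, min_prefix = 1) {
  cache <- attr(records, "cv_cache")
  if (is.null(cache)) abort("records must carry a cv cache (use evaluate_learners()).")
  if (length(S_star) < 1L) abort("S_star must be non-empty.")
  min_prefix <- max(1L, as.integer(min_prefix))
  if (min_prefix > length(S_star)) abort("min_prefix exceeds the pool size.")
  acc_map <- setNames(records$mean_cv_accuracy, records$pathway_id)
  sizes <- seq.int(min_prefix, length(S_star))
  accs <- vapply(sizes, function(sz) {
    members <- S_star[seq_len(sz)]
    tb <- tie_break_member(members, acc_map)
    mean(cache_ensemble_accuracy(cache, members, cache$positive_label, tb))
  }, numeric(1L))
  m <- sizes[which.max(accs)] # which.max takes the first (smallest) maximum
  list(
    m = as.integer(m),
    prefix_accuracies = tibble::tibble(size = as.integer(sizes), accuracy = accs),
    S_prime = S_star[seq_len(m)]
  )
}

#' Prune low-diversity learner pairs from the ensemble
#'
#' The second optimization: while some surviving, not-yet-considered pair
#' has diversity below the threshold `theta`, the lowest-diversity such pair
#' `(i, k)` is examined and four candidate ensembles are scored by the same
#' cross-validated majority vote — keep both (S1), drop `k` (S2), drop `i`
#' (S3), drop both (S4). The candidate with the highest mean accuracy wins;
#' on ties (within `eps`) the priority is S4 > S3 > S2 > S1, i.e. prefer
#' removing redundant members. The ensemble is never reduced below one
#' member, each pair is considered at most once, and survivors keep their
#' S' order.
#'
#' @param records A `learner_records` tibble carrying the cv cache.
#' @param S_prime Character vector: the prefix ensemble to prune.
#' @param D Diversity matrix covering `S_prime`.
#' @param theta Diversity threshold in `[0, 1]`; default 0.15.
#' @param eps Accuracy-tie tolerance; default 1e-6.
#' @return A list with `S_doubleprime` (surviving IDs in `S_prime` order)
#'   and `removed_pairs` (tibble with one row per examined pair: `i`, `k`,
#'   `diversity`, `option`, and the four candidate accuracies `acc_S1` ...
#'   `acc_S4`; `acc_S4` is `NA` when dropping both was infeasible).
#' @export
prune_ensemble <- function(records, S_prime, D, theta = 0.15, eps = 1e-6) {
  cache <- attr(records, "cv_cache")
  if (is.null(cache)) abort("records must carry a cv cache (use evaluate_learners()).")
  if (theta < 0 || theta > 1) abort("theta must be in [0, 1].")
  if (!all(S_prime %in% rownames(D))) abort("D must cover every member of S_prime.")
  acc_map <- setNames(records$mean_cv_accuracy, records$pathway_id)
  score <- function(members) {
    tb <- tie_break_member(members, acc_map)
    mean(cache_ensemble_accuracy(cache, members, cache$positive_label, tb))
  }
  survivors <- S_prime
  considered <- character(0)
  log <- list()

  repeat {
    if (length(survivors) < 2L) break
    pairs <- utils::combn(survivors, 2L)
    keys <- apply(pairs, 2L, paste, collapse = "|")
    divs <- D[cbind(pairs[1L, ], pairs[2L, ])]
    open <- which(divs < theta & !(keys %in% considered))
    if (length(open) == 0L) break
    # most redundant pair first; lexicographic pair key breaks diversity ties
    pick <- open[order(divs[open], keys[open])][1L]
    i <- pairs[1L, pick]
    k <- pairs[2L, pick]
    considered <- c(considered, keys[pick])

    cand <- list(
      S1 = survivors,
      S2 = setdiff(survivors, k),
      S3 = setdiff(survivors, i),
      S4 = if (length(survivors) > 2L) setdiff(survivors, c(i, k)) else NULL
    )
    accs <- vapply(cand, function(m) if (is.null(m)) NA_real_ else score(m),
                   numeric(1L))
    best <- max(accs, na.rm = TRUE)
    # S4 > S3 > S2 > S1 among candidates tied with the best accuracy
    for (opt in c("S4", "S3", "S2", "S1")) {
      if (!is.na(accs[[opt]]) && accs[[opt]] >= best - eps) {
        chosen <- opt
        break
      }
    }
    survivors <- cand[[chosen]]
    log[[length(log) + 1L]] <- tibble::tibble(
      i = i, k = k, diversity = unname(divs[pick]), option = chosen,
      acc_S1 = accs[["S1"]], acc_S2 = accs[["S2"]],
      acc_S3 = accs[["S3"]], acc_S4 = accs[["S4"]]
    )
  }

  list(
    S_doubleprime = S_prime[S_prime %in% survivors],
    removed_pairs = if (length(log) > 0L) {
      dplyr::bind_rows(log)
    } else {
      tibble::tibble(
        i = character(0), k = character(0), diversity = numeric(0),
        option = character(0), acc_S1 = numeric(0), acc_S2 = numeric(0),
        acc_S3 = numeric(0), acc_S4 = numeric(0)
      )
    }
  )
}

#' Fit the full diversity-optimized pathway ensemble
#'
#' End-to-end training: differential-expression screening on the training
#' set, pathway-to-DE-gene mapping, one SVM base learner per DE pathway
#' scored by repeated balanced cross-validation, accuracy ranking into the
#' top-N pool S, pairwise disagreement diversity averaged over the
#' resampling runs, reordering by overall diversity into S*, incremental
#' prefix search for the best ensemble size m (S'), and threshold pruning of
#' low-diversity pairs (S''). The surviving learners are retrained once on a
#' seeded balanced subsample of the full training set and combined by
#' majority vote.
#'
#' @param train A labeled training [expression_dataset()].
#' @param gene_sets A `gene_set_collection` (pathway ID -> member genes).
#' @param alpha DE screening p-value cutoff; default 0.05.
#' @param top_n Size of the accuracy-ranked pool S; default 35.
#' @param theta Diversity pruning threshold; default 0.15.
#' @param protocol A [cv_protocol()]; its seed is the master seed of the
#'   whole fit.
#' @param kernel SVM kernel, `"radial"` or `"linear"`.
#' @param min_prefix Smallest prefix size evaluated in the preliminary
#'   optimization; default 1.
#' @param de_method DE test, `"moderated"` (default) or `"welch"`.
#' @return A `pathway_ensemble` object: final learners (with fitted SVMs),
#'   the complete selection trace, the DE table, the learner records, and
#'   the configuration. Supports [predict()], [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' \donttest{
#' sim <- simulate_expression(simulation_config(
#'   n_genes = 300, n_pathways = 12, n_informative_pathways = 3,
#'   delta = 2, n_pos = 30, n_neg = 30, seed = 11))
#' fit <- fit_pathway_ensemble(sim$dataset, sim$gene_sets,
#'   protocol = cv_protocol(n_runs = 5, seed = 11))
#' fit
#' }
#' @export
fit_pathway_ensemble <- function(train, gene_sets, alpha = 0.05, top_n = 35,
                                 theta = 0.15, protocol = cv_protocol(),
                                 kernel = c("radial", "linear"),
                                 min_prefix = 1,
                                 de_method = c("moderated", "welch")) {
  stopifnot(inherits(train, "expression_dataset"))
  kernel <- match.arg(kernel)
  de_method <- match.arg(de_method)

  de <- screen_de_genes(train, alpha = alpha, method = de_method)
  de_pathways <- map_pathways_to_de(gene_sets, de, universe = gene_ids(train))
  records <- evaluate_learners(train, de_pathways, protocol, kernel = kernel)
  ranked <- rank_learners(records, top_n = top_n)
  S <- ranked$pathway_id

  cache <- attr(records, "cv_cache")
  if (length(S) >= 2L) {
    D <- cache_diversity_matrix(cache, S)
    od <- overall_diversity(D)
    S_star <- reorder_by_od(S, od)
    prelim <- preliminary_optimize(records, S_star, min_prefix = min_prefix)
    pruned <- prune_ensemble(records, prelim$S_prime, D, theta = theta)
  } else {
    D <- matrix(0, 1L, 1L, dimnames = list(S, S))
    od <- setNames(0, S)
    S_star <- S
    prelim <- list(m = 1L,
                   prefix_accuracies = tibble::tibble(
                     size = 1L, accuracy = ranked$mean_cv_accuracy[1L]),
                   S_prime = S)
    pruned <- list(S_doubleprime = S,
                   removed_pairs = prune_ensemble_empty_log())
  }

  final_ids <- pruned$S_doubleprime
  # one retraining pass on a seeded balanced subsample of the full training set
  final_train <- if (protocol$balance) {
    balanced_subsample(train, derive_seed(protocol$seed, STAGE[["final_fit"]]))
  } else {
    train
  }
  acc_map <- setNames(records$mean_cv_accuracy, records$pathway_id)
  feat_map <- setNames(records$feature_genes, records$pathway_id)
  learners <- lapply(setNames(final_ids, final_ids), function(id) {
    list(
      pathway_id = id,
      feature_genes = feat_map[[id]],
      mean_cv_accuracy = unname(acc_map[[id]]),
      svm = train_svm(final_train, feat_map[[id]], kernel = kernel)
    )
  })

  trace <- list(
    S = S, S_star = S_star,
    prefix_accuracies = prelim$prefix_accuracies,
    m = prelim$m, S_prime = prelim$S_prime,
    removed_pairs = pruned$removed_pairs,
    S_doubleprime = final_ids, theta = theta
  )
  structure(
    list(
      learners = learners,
      positive_label = train$positive_label,
      class_labels = sort(unique(unname(train$labels))),
      trace = trace,
      diversity = D,
      overall_diversity = od,
      de = de,
      records = records,
      config = list(alpha = alpha, top_n = top_n, theta = theta,
                    protocol = protocol, kernel = kernel,
                    min_prefix = min_prefix, de_method = de_method)
    ),
    class = "pathway_ensemble"
  )
}

prune_ensemble_empty_log <- function() {
  tibble::tibble(
    i = character(0), k = character(0), diversity = numeric(0),
    option = character(0), acc_S1 = numeric(0), acc_S2 = numeric(0),
    acc_S3 = numeric(0), acc_S4 = numeric(0)
  )
}

#' @export
print.pathway_ensemble <- function(x, ...) {
  tr <- x$trace
  cat(sprintf(
    "<pathway_ensemble> %d member(s), majority vote (positive: %s)\n",
    length(x$learners), x$positive_label
  ))
  cat(sprintf(
    "  DE genes: %d | DE pathways scored: %d | pool |S| = %d | m = %d | final |S''| = %d\n",
    sum(x$de$is_de), nrow(x$records), length(tr$S), tr$m,
    length(tr$S_doubleprime)
  ))
  cat(sprintf("  members: %s\n", paste(tr$S_doubleprime, collapse = ", ")))
  invisible(x)
}

#' Predict class labels with a fitted pathway ensemble
#'
#' Each member SVM predicts every sample from its own feature genes; the
#' ensemble label is the majority vote, even-split ties going to the member
#' with the highest training cross-validation accuracy.
#'
#' @param object A `pathway_ensemble`.
#' @param newdata An [expression_dataset()] (labels optional) containing
#'   every member's feature genes.
#' @param ... Unused.
#' @return Named character vector of predicted labels, one per sample.
#' @export
predict.pathway_ensemble <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "expression_dataset"))
  for (l in object$learners) {
    missing <- setdiff(l$feature_genes, gene_ids(newdata))
    if (length(missing) > 0L) {
      abort(sprintf(
        "test matrix lacks gene '%s' needed by pathway '%s'.",
        missing[1L], l$pathway_id
      ))
    }
  }
  pred <- do.call(cbind, lapply(object$learners, function(l) {
    predict(l$svm, newdata)
  }))
  rownames(pred) <- sample_ids(newdata)
  acc_map <- vapply(object$learners, `[[`, numeric(1L), "mean_cv_accuracy")
  tb <- tie_break_member(names(object$learners), acc_map)
  out <- apply(pred, 1L, function(v) majority_vote(v, tie_break = tb))
  setNames(out, sample_ids(newdata))
}
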