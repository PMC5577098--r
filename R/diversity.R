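#' Disagreement between two classifier correctness vectors
#'
#' The disagreement measure for a pair of classifiers over a labeled sample
#' set: the fraction of samples on which exactly one of the two classifiers
#' is correct,
#' `D = (N01 + N10) / (N11 + N10 + N01 + N00)`,
#' where `N^ab` counts samples with correctness `a` under the first
#' classifier and `b` under the second. Equals the normalized Hamming
#' distance between the two 0/1 vectors, so it is symmetric, lies in
#' `[0, 1]`, and is 0 iff the vectors coincide.
#'
#' @param y_i,y_k Binary (0/1) correctness vectors of equal positive length.
#'   If both are named, names must agree (aligned samples).
#' @return The disagreement, a scalar in `[0, 1]`.
#' @examples
#' disagreement(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 0.5
#' @export
disagreement <- function(y_i, y_k) {
  if (length(y_i) == 0L) abort("correctness vectors must be non-empty.")
  if (length(y_i) != length(y_k)) {
    abort(sprintf("length mismatch: %d vs %d.", length(y_i), length(y_k)))
  }
  if (!is.null(names(y_i)) && !is.null(names(y_k)) &&
      !identical(names(y_i), names(y_k))) {
    abort("correctness vectors are not aligned (sample names differ).")
  }
  if (!all(y_i %in% c(0, 1)) || !all(y_k %in% c(0, 1))) {
    abort("correctness vectors must be binary (0/1).")
  }
  mean(y_i != y_k)
}

#' Pairwise diversity matrix of a set of base learners
#'
#' Builds the symmetric N x N matrix of pairwise disagreements. With a
#' single set of correctness vectors the entries are plain disagreements;
#' with several repeats (one fresh set of correctness vectors per balanced
#' resample) the entries are averaged over repeats, matching the protocol of
#' computing the pairwise diversities many times and taking the mean.
#'
#' @param vectors Either a list of aligned binary correctness vectors (one
#'   per learner), or a list of such lists (one inner list per repeat, all
#'   repeats covering the same learners in the same order).
#' @return A symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1]`, dimnames taken from the learner names when present.
#' @export
diversity_matrix <- function(vectors) {
  if (length(vectors) == 0L) abort("no correctness vectors supplied.")
  repeats <- if (is.list(vectors[[1L]])) vectors else list(vectors)
  n_learners <- length(repeats[[1L]])
  if (n_learners < 2L) abort("need >= 2 learners to form a diversity matrix.")
  ids <- names(repeats[[1L]]) %||% paste0("h", seq_len(n_learners))
  acc <- matrix(0, n_learners, n_learners, dimnames = list(ids, ids))
  for (rep_vectors in repeats) {
    if (length(rep_vectors) != n_learners) {
      abort("every repeat must cover the same learners.")
    }
    lens <- lengths(rep_vectors)
    if (length(unique(lens)) != 1L) {
      abort("inconsistent correctness-vector lengths across learners.")
    }
    y <- do.call(cbind, rep_vectors)
    # normalized Hamming distances between all column pairs
    d <- as.matrix(stats::dist(t(y), method = "manhattan")) / nrow(y)
    acc <- acc + d
  }
  out <- acc / length(repeats)
  dimnames(out) <- list(ids, ids)
  out
}

#' Overall diversity of each learner
#'
#' The row aggregate of the diversity matrix,
#' `OD[i] = sum_j (D[i, j] + D[j, i])`, implemented as the literal double
#' sum (the zero diagonal contributes nothing); for a symmetric matrix this
#' equals twice the row sums. Learners with high overall diversity disagree
#' most with the rest of the pool.
#'
#' @param D A diversity matrix from [diversity_matrix()] (square; a 1 x 1
#'   matrix gives OD = 0).
#' @return Named numeric vector of length `nrow(D)`.
#' @export
overall_diversity <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be a square matrix.")
  od <- vapply(seq_len(nrow(D)), function(i) sum(D[i, ] + D[, i]),
               numeric(1L))
  setNames(od, rownames(D))
}

# Diversity matrix averaged over the runs of a cv cache: per run, each
# learner's correctness on that run's balanced subsample (every subsample
# sample is held out exactly once under k-fold).
cache_diversity_matrix <- function(cache, learner_ids = cache$learner_ids) {
  repeats <- lapply(cache$runs, function(run) {
    hit <- (run$pred[, learner_ids, drop = FALSE] == run$truth) * 1L
    lapply(setNames(learner_ids, learner_ids), function(id) hit[, id])
  })
  diversity_matrix(repeats)
}
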