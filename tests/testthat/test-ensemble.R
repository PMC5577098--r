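test_that("OD reordering is a stable descending sort", {
  od <- c(A = 1.2, B = 1.6, C = 2.0)
  expect_equal(reorder_by_od(c("A", "B", "C"), od), c("C", "B", "A"))
  flat <- c(A = 1, B = 1, C = 1)
  expect_equal(reorder_by_od(c("B", "A", "C"), flat), c("B", "A", "C"))
  expect_equal(reorder_by_od("A", c(A = 0)), "A")
  expect_error(reorder_by_od(c("A", "Z"), od), "cover")
})

test_that("majority vote needs a strict majority, ties go to the tie-breaker", {
  expect_equal(majority_vote(c("pos", "pos", "neg")), "pos")
  v <- c(h1 = "pos", h2 = "pos", h3 = "neg", h4 = "neg")
  expect_equal(majority_vote(v, tie_break = "h3"), "neg")
  expect_equal(majority_vote(v, tie_break = "h1"), "pos")
  expect_error(majority_vote(character(0)), "at least one")
})

test_that("ensemble correctness threshold is floor(T/2 + 1) for odd pools", {
  for (T_ in c(1L, 3L, 5L, 7L)) {
    patterns <- all_binary_vectors(T_)
    for (i in seq_len(nrow(patterns))) {
      correct <- patterns[i, ]
      votes <- ifelse(correct == 1L, "truth", "other")
      expect_identical(
        majority_vote(votes) == "truth",
        sum(correct) >= floor(T_ / 2 + 1)
      )
    }
  }
})

test_that("degenerate ensembles reduce to their single distinct member", {
  sim <- make_small_sim(seed = 41, delta = 2)
  de <- screen_de_genes(sim$dataset)
  dp <- map_pathways_to_de(sim$gene_sets, de)
  prot <- cv_protocol(n_runs = 3, seed = 41)
  fs <- setNames(dp$feature_genes, dp$pathway_id)[1]

  single <- evaluate_ensemble_cv(sim$dataset, fs, prot)
  solo <- evaluate_learner_cv(sim$dataset, fs[[1L]], prot)
  expect_equal(single$mean_accuracy, solo$mean_cv_accuracy)

  triple <- setNames(rep(fs, 3), c("a", "b", "c"))
  expect_equal(evaluate_ensemble_cv(sim$dataset, triple, prot)$mean_accuracy,
               single$mean_accuracy)

  sep <- make_separable_dataset()
  expect_equal(
    evaluate_ensemble_cv(sep, list(pw = rownames(sep$values)[1:4]),
                         cv_protocol(n_runs = 2, seed = 1))$mean_accuracy,
    1
  )
})

test_that("cached ensemble scoring equals naive re-evaluation", {
  sim <- make_small_sim(seed = 55, delta = 1.5)
  de <- screen_de_genes(sim$dataset)
  dp <- map_pathways_to_de(sim$gene_sets, de)
  prot <- cv_protocol(n_runs = 4, seed = 55)
  records <- evaluate_learners(sim$dataset, dp, prot)
  cache <- attr(records, "cv_cache")
  acc_map <- setNames(records$mean_cv_accuracy, records$pathway_id)
  members <- head(records$pathway_id, 3L)
  tb <- members[order(-acc_map[members], members)][1L]

  cached <- mean(pathvote:::cache_ensemble_accuracy(
    cache, members, cache$positive_label, tb))
  naive <- evaluate_ensemble_cv(
    sim$dataset, setNames(records$feature_genes, records$pathway_id)[members],
    prot)$mean_accuracy
  expect_equal(cached, naive)
})

test_that("prefix search returns the smallest best prefix", {
  sep <- make_separable_dataset(n_genes = 20, n_per_class = 10, seed = 2)
  noise <- make_null_dataset(n_genes = 20, n_per_class = 10, seed = 2)
  # one perfect learner (separable genes) + two noise learners
  values <- rbind(sep$values[1:5, ], noise$values)
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- colnames(sep$values)
  ds <- expression_dataset(values, sep$labels, positive_label = "pos")
  dp <- tibble::tibble(
    pathway_id = c("perfect", "noiseA", "noiseB"),
    feature_genes = list(paste0("g", 1:5), paste0("g", 6:15),
                         paste0("g", 16:25))
  )
  prot <- cv_protocol(n_runs = 4, seed = 2)
  records <- evaluate_learners(ds, dp, prot)
  res <- preliminary_optimize(records, c("perfect", "noiseA", "noiseB"))
  expect_equal(res$m, 1L)
  expect_equal(res$S_prime, "perfect")
  expect_equal(res$prefix_accuracies$size, 1:3)
  expect_equal(max(res$prefix_accuracies$accuracy),
               res$prefix_accuracies$accuracy[1L])

  # identical learners: flat curve, smallest-prefix tie rule gives m = 1
  dup <- tibble::tibble(
    pathway_id = c("a", "b", "c"),
    feature_genes = list(paste0("g", 1:5), paste0("g", 1:5), paste0("g", 1:5))
  )
  rec2 <- evaluate_learners(ds, dup, prot)
  res2 <- preliminary_optimize(rec2, c("a", "b", "c"))
  expect_equal(res2$m, 1L)
  expect_equal(length(unique(res2$prefix_accuracies$accuracy)), 1L)
})

test_that("pruning leaves high-diversity ensembles untouched and removes duplicates", {
  sim <- make_small_sim(seed = 77, delta = 2)
  de <- screen_de_genes(sim$dataset)
  dp <- map_pathways_to_de(sim$gene_sets, de)
  prot <- cv_protocol(n_runs = 3, seed = 77)
  records <- evaluate_learners(sim$dataset, dp, prot)
  ids <- head(records$pathway_id, 3L)

  # nothing qualifies below theta = 0
  D_high <- matrix(0.5, 3, 3, dimnames = list(ids, ids))
  diag(D_high) <- 0
  res <- prune_ensemble(records, ids, D_high, theta = 0.15)
  expect_equal(res$S_doubleprime, ids)
  expect_equal(nrow(res$removed_pairs), 0L)

  # exact duplicate learners (D = 0, identical accuracy) collapse via S4/S2
  base <- records$feature_genes[[1L]]
  dup <- tibble::tibble(
    pathway_id = c("orig", "copy1", "copy2"),
    feature_genes = list(base, base, base)
  )
  rec2 <- evaluate_learners(sim$dataset, dup, prot)
  D0 <- matrix(0, 3, 3, dimnames = list(dup$pathway_id, dup$pathway_id))
  res2 <- prune_ensemble(rec2, dup$pathway_id, D0, theta = 0.15)
  expect_lt(length(res2$S_doubleprime), 3L)
  expect_gte(length(res2$S_doubleprime), 1L)
  expect_true(all(res2$removed_pairs$option %in% c("S2", "S3", "S4")))
  expect_error(prune_ensemble(records, ids, D_high, theta = 2), "theta")
})

test_that("the fitted ensemble trace satisfies its invariants and is deterministic", {
  sim <- make_small_sim(seed = 91, delta = 2, n_pathways = 10,
                        n_informative = 3)
  prot <- cv_protocol(n_runs = 4, seed = 91)
  fit <- fit_pathway_ensemble(sim$dataset, sim$gene_sets, protocol = prot,
                              top_n = 8)
  tr <- fit$trace
  expect_setequal(tr$S_star, tr$S)
  expect_true(all(tr$S_prime %in% tr$S_star))
  expect_true(all(tr$S_doubleprime %in% tr$S_prime))
  expect_equal(length(tr$S_prime), tr$m)
  expect_gte(length(tr$S_doubleprime), 1L)
  expect_equal(tr$S_prime, tr$S_star[seq_len(tr$m)])

  # surviving low-diversity pairs must carry a recorded S1 retention
  surv <- tr$S_doubleprime
  if (length(surv) >= 2L) {
    pairs <- utils::combn(surv, 2L)
    for (j in seq_len(ncol(pairs))) {
      d <- fit$diversity[pairs[1L, j], pairs[2L, j]]
      if (d < tr$theta) {
        kept <- tr$removed_pairs$option == "S1" &
          ((tr$removed_pairs$i == pairs[1L, j] &
              tr$removed_pairs$k == pairs[2L, j]) |
             (tr$removed_pairs$i == pairs[2L, j] &
                tr$removed_pairs$k == pairs[1L, j]))
        expect_true(any(kept))
      }
    }
  }

  fit2 <- fit_pathway_ensemble(sim$dataset, sim$gene_sets, protocol = prot,
                               top_n = 8)
  expect_identical(fit$trace, fit2$trace)
})

test_that("prediction is a column-order-invariant majority vote", {
  sep <- make_separable_dataset()
  fit <- fit_pathway_ensemble(
    sep,
    structure(list(pwA = rownames(sep$values)[1:4],
                   pwB = rownames(sep$values)[5:8]),
              class = c("gene_set_collection", "list")),
    protocol = cv_protocol(n_runs = 2, seed = 3), top_n = 2
  )
  pred <- predict(fit, sep)
  expect_equal(unname(pred), unname(sep$labels))

  shuffled <- pathvote:::subset_samples(sep, rev(colnames(sep$values)))
  pred_rev <- predict(fit, shuffled)
  expect_equal(pred_rev[names(pred)], pred)

  missing <- pathvote:::subset_samples(sep, colnames(sep$values))
  missing$values <- missing$values[-1, , drop = FALSE]
  expect_error(predict(fit, missing), "pw")
})

test_that("the ensemble is at least as good as its best member on test data", {
  wins <- vapply(1:5, function(s) {
    sim <- make_small_sim(seed = 200 + s, delta = 2, n_pathways = 8,
                          n_informative = 3, n_per_class = 30)
    halves <- split_dataset(sim$dataset, 0.5, seed = s)
    prot <- cv_protocol(n_runs = 4, seed = s)
    fit <- fit_pathway_ensemble(halves$train, sim$gene_sets, protocol = prot,
                                top_n = 6)
    truth <- halves$test$labels
    ens_acc <- mean(predict(fit, halves$test) == truth)
    rec <- fit$records
    best_id <- rank_learners(rec, 1)$pathway_id
    best_fit <- train_svm(
      balanced_subsample(halves$train,
                         pathvote:::derive_seed(prot$seed, 4L)),
      rec$feature_genes[[match(best_id, rec$pathway_id)]]
    )
    single_acc <- mean(predict(best_fit, halves$test) == truth)
    ens_acc >= single_acc
  }, logical(1L))
  expect_gte(mean(wins), 0.6)
})
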