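test_that("separable data is learned perfectly", {
  ds <- make_separable_dataset()
  fit <- train_svm(ds, rownames(ds$values)[1:5])
  expect_equal(unname(predict(fit, ds)), unname(ds$labels))

  res <- evaluate_learner_cv(ds, rownames(ds$values)[1:5],
                             cv_protocol(n_runs = 3, seed = 1))
  expect_equal(res$mean_cv_accuracy, 1)
  expect_true(all(res$correctness == 1L))
})

test_that("null data scores at chance under balanced CV", {
  ds <- make_null_dataset(n_genes = 30, n_per_class = 25, seed = 17)
  res <- evaluate_learner_cv(ds, rownames(ds$values)[1:10],
                             cv_protocol(n_runs = 20, seed = 17))
  expect_lt(abs(res$mean_cv_accuracy - 0.5), 0.05)
})

test_that("balanced subsampling keeps the minority class whole", {
  sim <- simulate_expression(simulation_config(
    n_genes = 30, n_pathways = 2, pathway_size_range = c(5, 10),
    n_informative_pathways = 1, n_pos = 50, n_neg = 195, seed = 6))
  bal <- balanced_subsample(sim$dataset, seed = 6)
  expect_equal(unname(table(bal$labels)[c("pCR", "RD")]), c(50L, 50L),
               ignore_attr = TRUE)
  pos_ids <- names(sim$dataset$labels)[sim$dataset$labels == "pCR"]
  expect_true(all(pos_ids %in% colnames(bal$values)))

  again <- balanced_subsample(sim$dataset, seed = 6)
  expect_identical(colnames(again$values), colnames(bal$values))

  even <- make_null_dataset(n_genes = 10, n_per_class = 8)
  expect_setequal(colnames(balanced_subsample(even, 1)$values),
                  colnames(even$values))
})

test_that("training requires two classes and known genes", {
  ds <- make_separable_dataset()
  single <- ds
  single$labels[] <- "pos"
  single <- structure(list(values = ds$values, labels = single$labels,
                           positive_label = "pos"),
                      class = "expression_dataset")
  expect_error(train_svm(single, rownames(ds$values)[1:2]), "single-class")
  expect_error(train_svm(ds, c("g1", "nope")), "nope")
})

test_that("ranking sorts by accuracy with lexicographic ties and a size cap", {
  rec <- tibble::tibble(
    pathway_id = c("pwC", "pwA", "pwB"),
    feature_genes = list("g1", "g2", "g3"),
    n_features = 1L,
    mean_cv_accuracy = c(0.7, 0.8, 0.8),
    sd_cv_accuracy = 0,
    correctness = list(1L, 1L, 1L)
  )
  top2 <- rank_learners(rec, top_n = 2)
  expect_equal(top2$pathway_id, c("pwA", "pwB"))
  expect_equal(top2$rank, 1:2)
  expect_warning(all3 <- rank_learners(rec, top_n = 35), "keeping all")
  expect_equal(all3$pathway_id, c("pwA", "pwB", "pwC"))
  expect_error(rank_learners(rec[0, ], 5), "no learner")
})

test_that("learner evaluation is reproducible and pathway-comparable", {
  sim <- make_small_sim(seed = 33, delta = 2)
  de <- screen_de_genes(sim$dataset)
  dp <- map_pathways_to_de(sim$gene_sets, de)
  prot <- cv_protocol(n_runs = 4, seed = 33)
  a <- evaluate_learners(sim$dataset, dp, prot)
  b <- evaluate_learners(sim$dataset, dp, prot)
  expect_identical(a$mean_cv_accuracy, b$mean_cv_accuracy)
  expect_identical(a$correctness, b$correctness)
  expect_true(all(a$mean_cv_accuracy >= 0 & a$mean_cv_accuracy <= 1))
  # single-learner path agrees with the multi-learner pass (shared streams)
  solo <- evaluate_learner_cv(sim$dataset, dp$feature_genes[[1L]], prot)
  expect_equal(solo$mean_cv_accuracy, a$mean_cv_accuracy[1L])
  expect_equal(unname(solo$correctness), unname(a$correctness[[1L]]))
})

test_that("informative pathways rise to the top ranks", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_expression(simulation_config(
      n_genes = 600, n_pathways = 12, pathway_size_range = c(8, 20),
      n_informative_pathways = 3, delta = 2, rho = 0.3,
      n_pos = 30, n_neg = 30, seed = 100 + s))
    de <- screen_de_genes(sim$dataset)
    dp <- map_pathways_to_de(sim$gene_sets, de)
    rec <- evaluate_learners(sim$dataset, dp, cv_protocol(n_runs = 5, seed = s))
    top3 <- rank_learners(rec, 3)$pathway_id
    mean(top3 %in% sim$informative_pathways)
  }, numeric(1L))
  expect_gte(mean(hits >= 2 / 3), 0.8)
})
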