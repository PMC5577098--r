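test_that("confusion counts follow the positive-label convention", {
  truth <- c(rep("p", 4), rep("n", 3))
  expect_equal(confusion(truth, truth, "p"),
               c(TP = 4L, TN = 3L, FP = 0L, FN = 0L))
  flipped <- ifelse(truth == "p", "n", "p")
  expect_equal(confusion(flipped, truth, "p"),
               c(TP = 0L, TN = 0L, FP = 3L, FN = 4L))
  # swapping the positive label swaps TP/TN and FP/FN
  pred <- c("p", "n", "p", "p", "n", "p", "n")
  a <- confusion(pred, truth, "p")
  b <- confusion(pred, truth, "n")
  expect_equal(unname(a[c("TP", "TN", "FP", "FN")]),
               unname(b[c("TN", "TP", "FN", "FP")]))
  expect_error(confusion(c("p", "n"), truth, "p"), "mismatch")
})

test_that("the five metrics match their formulas on a worked example", {
  m <- compute_metrics(c(TP = 3, TN = 2, FP = 1, FN = 1))
  expect_equal(setNames(m$value, m$metric),
               c(accuracy = 5 / 7, precision = 3 / 4, sensitivity = 3 / 4,
                 specificity = 2 / 3, f_score = 6 / 8))

  perfect <- compute_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_true(all(perfect$value == 1))

  # no positives anywhere: sensitivity undefined, specificity defined
  deg <- compute_metrics(c(TP = 0, TN = 4, FP = 0, FN = 0))
  vals <- setNames(deg$value, deg$metric)
  expect_true(is.na(vals["sensitivity"]))
  expect_equal(unname(vals["specificity"]), 1)
  expect_error(compute_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "sum")
})

test_that("F-score is the harmonic mean of precision and sensitivity", {
  withr::with_seed(14, {
    for (i in 1:200) {
      cts <- setNames(rpois(4, 5), c("TP", "TN", "FP", "FN"))
      if (sum(cts) == 0) next
      m <- setNames(compute_metrics(cts)$value, compute_metrics(cts)$metric)
      if (!is.na(m["precision"]) && !is.na(m["sensitivity"]) &&
          (m["precision"] + m["sensitivity"]) > 0) {
        expect_equal(
          unname(m["f_score"]),
          unname(2 * m["precision"] * m["sensitivity"] /
                   (m["precision"] + m["sensitivity"]))
        )
      }
      expect_equal(unname(m["accuracy"]), sum(cts[c("TP", "TN")]) / sum(cts))
    }
  })
})

test_that("test-set evaluation is balanced, deterministic and model-fixed", {
  sim <- make_small_sim(seed = 61, delta = 3, n_per_class = 30)
  halves <- split_dataset(sim$dataset, 0.5, seed = 61)
  fit <- fit_pathway_ensemble(halves$train, sim$gene_sets,
                              protocol = cv_protocol(n_runs = 3, seed = 61),
                              top_n = 5)
  rep1 <- evaluate_on_test(fit, halves$test, cv_protocol(n_runs = 5, seed = 9))
  rep2 <- evaluate_on_test(fit, halves$test, cv_protocol(n_runs = 5, seed = 9))
  expect_identical(rep1$runs, rep2$runs)
  expect_equal(nrow(rep1$runs), 5L)
  expect_true(all(rep1$summary$mean >= 0 & rep1$summary$mean <= 1))
  expect_equal(rep1$summary$metric[1L], "accuracy")

  # separable data: every metric 1 with zero spread
  sep <- make_separable_dataset(n_genes = 12, n_per_class = 10)
  fit_sep <- fit_pathway_ensemble(
    sep,
    structure(list(pw = rownames(sep$values)[1:6]),
              class = c("gene_set_collection", "list")),
    protocol = cv_protocol(n_runs = 2, seed = 4), top_n = 1
  )
  rep_sep <- evaluate_on_test(fit_sep, sep, cv_protocol(n_runs = 4, seed = 4))
  expect_true(all(rep_sep$summary$mean == 1))
  expect_true(all(rep_sep$summary$sd == 0))

  g <- glance(rep1)
  expect_equal(names(g),
               c("accuracy", "precision", "sensitivity", "specificity",
                 "f_score"))
})

test_that("metric summaries are invariant to sample order", {
  sim <- make_small_sim(seed = 71, delta = 2, n_per_class = 24)
  halves <- split_dataset(sim$dataset, 0.5, seed = 71)
  fit <- fit_pathway_ensemble(halves$train, sim$gene_sets,
                              protocol = cv_protocol(n_runs = 2, seed = 71),
                              top_n = 4)
  fwd <- evaluate_on_test(fit, halves$test, cv_protocol(n_runs = 4, seed = 2))
  rev_test <- pathvote:::subset_samples(
    halves$test, rev(colnames(halves$test$values)))
  bwd <- evaluate_on_test(fit, rev_test, cv_protocol(n_runs = 4, seed = 2))
  expect_equal(fwd$summary$mean, bwd$summary$mean)
})
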