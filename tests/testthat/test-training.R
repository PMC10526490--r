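# cross-validation, metrics, and the training loop

test_that("ratings binarize at the midpoint with ties going low", {
  expect_equal(binarize_ratings(c(7.5, 3.0)), c(1L, 0L))
  expect_equal(binarize_ratings(5.0), 0L)
  expect_equal(binarize_ratings(5.0001), 1L)
  set.seed(1)
  scores <- runif(40, 1, 9)
  expect_length(binarize_ratings(scores), 40L)
  expect_error(binarize_ratings(c(2, 10)), "\\[1, 9\\]")
  expect_error(binarize_ratings(0.5), "\\[1, 9\\]")
})

test_that("k-fold plans partition samples into near-equal stratified folds", {
  labels <- rep(c(0L, 1L), each = 1200)
  plan <- make_folds(2400, "kfold", 5, labels = labels, seed = 3)
  expect_equal(sort(unique(plan$assignments)), 1:5)
  expect_equal(unname(tabulate(plan$assignments, 5)), rep(480L, 5))
  # stratification: each fold holds 240 of each class
  for (f in 1:5)
    expect_equal(sum(labels[plan$assignments == f] == 1L), 240L)
  # determinism
  plan2 <- make_folds(2400, "kfold", 5, labels = labels, seed = 3)
  expect_identical(plan$assignments, plan2$assignments)
  expect_false(identical(
    plan$assignments, make_folds(2400, "kfold", 5, labels = labels,
                                 seed = 4)$assignments))
  expect_error(make_folds(10, "kfold", 1), ">= 2")
  expect_error(make_folds(3, "kfold", 5), "exceeds")
})

test_that("fold sizes differ by at most one across random cases", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    k <- sample(2:min(10, n), 1)
    plan <- make_folds(n, "kfold", k, seed = i)
    sizes <- tabulate(plan$assignments, k)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_equal(sum(sizes), n)
  }
})

test_that("leave-one-subject-out makes one fold per subject", {
  subjects <- rep(1:15, each = 4)
  plan <- make_folds(scheme = "loso", subjects = subjects)
  expect_equal(plan$n_folds, 15L)
  for (s in 1:15)
    expect_true(all(subjects[plan$assignments == s] == s))
  expect_error(make_folds(scheme = "loso"), "subjects")
})

test_that("metrics match the defining formulas", {
  r <- compute_metrics(c(TP = 50, TN = 40, FP = 5, FN = 5))
  expect_equal(r$accuracy, 90)
  expect_equal(r$precision, 100 * 50 / 55, tolerance = 1e-12)  # ~90.9%
  expect_equal(r$recall, 100 * 50 / 55, tolerance = 1e-12)
  expect_equal(r$f_score, 2 * r$precision * r$recall / (r$precision + r$recall))
  # perfect classification
  perfect <- compute_metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f_score")]),
               c(accuracy = 100, precision = 100, recall = 100, f_score = 100))
  # undefined precision reported as NA with a warning, not as 0
  expect_warning(und <- compute_metrics(c(TP = 0, TN = 10, FP = 0, FN = 5)),
                 "undefined")
  expect_true(is.na(und$precision))
  expect_error(compute_metrics(c(TP = -1, TN = 1, FP = 0, FN = 0)), "negative")
})

test_that("F-score lies between precision and recall; accuracy equals 1 - error rate", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    p <- sample(0:1, n, replace = TRUE)
    cc <- confusion_counts(y, p, 2)
    expect_equal(sum(cc[1, ]), n)
    r <- tryCatch(suppressWarnings(compute_metrics(cc)), error = identity)
    if (inherits(r, "error")) next
    expect_equal(r$accuracy, 100 * mean(y == p), tolerance = 1e-10)
    if (!is.na(r$f_score)) {
      expect_gte(r$f_score, min(r$precision, r$recall) - 1e-9)
      expect_lte(r$f_score, max(r$precision, r$recall) + 1e-9)
    }
  }
})

test_that("macro averaging over three classes", {
  y <- c(0, 0, 1, 1, 2, 2)
  p <- c(0, 1, 1, 1, 2, 0)
  cc <- confusion_counts(y, p, 3)
  r <- compute_metrics(cc)
  expect_equal(r$accuracy, 100 * 4 / 6, tolerance = 1e-10)
  # macro precision: class0 1/2, class1 2/3, class2 1/1
  expect_equal(r$precision, 100 * mean(c(1 / 2, 2 / 3, 1)), tolerance = 1e-10)
  expect_equal(r$recall, 100 * mean(c(1 / 2, 1, 1 / 2)), tolerance = 1e-10)
})

test_that("a tiny model learns an easy task and stays seed-reproducible", {
  ft <- featurized_study(easy_spec(n_subjects = 1L, n_trials = 6L,
                                   trial_seconds = 8))
  labels <- ft$meta$label
  cfg <- tiny_cfg()
  m1 <- train_model(ft, labels, cfg, epochs = 4, batch_size = 10, seed = 2)
  acc <- mean(predict_labels(m1, ft) == labels)
  expect_gte(acc, 0.9)  # training accuracy on a well-separated task
  expect_true(all(is.finite(m1$loss_log)))
  expect_lt(m1$loss_log[length(m1$loss_log)], m1$loss_log[1])
  # reproducibility: identical seeds give identical weights and predictions
  m2 <- train_model(ft, labels, cfg, epochs = 4, batch_size = 10, seed = 2)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_proba(m1, ft), predict_proba(m2, ft))
})

test_that("nearest-centroid baseline separates the easy generator setting", {
  ft <- featurized_study(easy_spec(n_subjects = 1L, n_trials = 6L,
                                   trial_seconds = 8))
  labels <- ft$meta$label
  n <- length(labels)
  half <- seq_len(n %/% 2)
  pred <- nearest_centroid(ft$grid[half, , , , drop = FALSE], labels[half],
                           ft$grid[-half, , , , drop = FALSE])
  expect_gte(mean(pred == labels[-half]), 0.85)
})

test_that("single-class training folds trigger a warning", {
  ft <- featurized_study(easy_spec(n_subjects = 1L, n_trials = 2L,
                                   trial_seconds = 5))
  labels <- ft$meta$label
  plan <- list(scheme = "kfold", assignments = ifelse(labels == 0L, 1L, 2L),
               n_folds = 2L, seed = 1L)
  class(plan) <- "fold_plan"
  expect_warning(
    train_and_evaluate(ft, labels, tiny_cfg(), plan, epochs = 1,
                       batch_size = 4),
    "single class")
})
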